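Behaviour,MinutesPerDay,MinutesPerDaySD,PercentOfDay,PercentOfDaySD,PeakStartHour,PeakEndHour,VisitsPerDay,VisitsPerDaySD,MinutesPerVisit,MinutesPerVisitSD
Motionless in Tree,385.2,194.3,26.8,13.5,7,8,NA,NA,NA,NA
General Movement in Tree,827.3,204.7,57.5,14.2,13,14,NA,NA,NA,NA
Feeding & Grooming in Tree,224.2,39.2,15.6,2.7,18,19,NA,NA,NA,NA
Walking,3,1.4,0.2,0.1,2,3,2.95,2.31,1.59,1.95
Other,0.2,0.5,NA,NA,NA,NA,NA,NA,NA,NA
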