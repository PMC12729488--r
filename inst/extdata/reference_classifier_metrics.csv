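Behaviour,Precision,Recall,F1,Accuracy,Prevalence
Class: Bellowing,0.791667,0.142857,0.242038,0.571197,133
Class: Climbing,0.780275,0.788146,0.784191,0.885394,793
Class: Feeding,0.762519,0.834025,0.796671,0.900923,1205
Class: Grooming,0.734861,0.683409,0.708202,0.824861,1314
Class: Still,0.998971,0.95334,0.975622,0.976558,2036
Class: In-tree Movement,0.765428,0.837678,0.799925,0.880148,2532
Class: Walking,0.991938,0.96951,0.980596,0.98332,2919
Macro-average,0.832237,0.744138,0.755321,0.860343,NA
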