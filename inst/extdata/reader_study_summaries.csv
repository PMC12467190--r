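question_id,mean,sd,median,iqr,n
Q1,4.5,0.55,4.5,1,6
Q2,4.5,0.55,4.5,1,6
Q3,4.67,0.52,5,0.75,6
Q4,4.5,0.84,5,0.75,6
Q5,4.33,0.52,4,0.75,6
Q6,4.33,0.52,4,0.75,6
Q7,3.83,0.41,4,0,6
Q8,3.83,0.75,4,0.75,6
Q9,4.83,0.41,5,0,6
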