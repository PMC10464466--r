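item_id,subscale,lambda_general,lambda_specific
SP1_Q1/SP2_Q1,Auditory,0.513,0.699
SP1_Q2/SP2_Q2,Auditory,0.469,0.683
SEQ2_Q1/SEQ3_Q1,Auditory,0.469,0.753
SEQ3_Q9,Auditory,0.611,0.475
SEQ2_Q8/SEQ3_Q15,Visual,0.571,0.594
SP1_Q10/SP2_Q15,Visual,0.563,0.677
SP1_Q14/SP2_Q13,Visual,0.649,0.601
SP1_Q15,Visual,0.565,0.599
SP1_Q30/SP2_Q16/SEQ2_Q15/SEQ3_Q49,Tactile,0.449,0.449
SP1_Q36/SP2_Q18,Tactile,0.608,0.261
SEQ2_Q16/SEQ3_Q38,Tactile,0.564,0.100
SP1_Q33,Tactile,0.650,0.324
SEQ2_Q22/SEQ3_Q59,Gustatory,0.451,0.695
SP1_Q55/SP2_Q44,Gustatory,0.465,0.786
SP1_Q56/SP2_Q45,Gustatory,0.454,0.721
SEQ3_Q70,Gustatory,0.482,0.393
SEQ3_Q61,Olfactory,0.619,0.685
SEQ3_Q66,Olfactory,0.543,0.713
SEQ3_Q73,Olfactory,0.547,0.413
SP1_Q18,Movement,0.482,0.701
SP1_Q19,Movement,0.462,0.680
SP1_Q20,Movement,0.408,0.637
SEQ3_Q83,Movement,0.464,0.621
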