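item_id,subscale,lambda_general,lambda_specific
SEQ2_Q3/SEQ3_Q8,Speech,0.436,0.730
SP1_Q6/SP2_Q6,Speech,0.318,0.737
SP1_Q7/SP2_Q7,Speech,0.421,0.848
SEQ2_Q19/SEQ3_Q53,PainTemperature,0.428,0.681
SP1_Q42/SP2_Q23/SP2_Q24,PainTemperature,0.469,0.854
SEQ3_Q56,PainTemperature,0.458,0.470
SEQ2_Q10/SEQ3_Q22/SEQ3_Q23,,0.537,
SP1_Q46/SP2_Q26,,0.473,
SEQ2_Q4/SEQ3_Q4,,0.547,
SP1_Q125,Olfactory,0.563,0.647
SEQ3_Q69,Olfactory,0.449,0.561
SEQ3_Q74,,0.444,
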