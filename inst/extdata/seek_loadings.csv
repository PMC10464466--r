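item_id,subscale,lambda_general,lambda_specific
SEQ2_Q9/SEQ3_Q17,Visual,0.681,0.421
SP1_Q97/SP2_Q80/SP2_Q81,Visual,0.592,0.297
SEQ3_Q19,Visual,0.663,0.326
SEQ3_Q27,Visual,0.543,0.563
SEQ3_Q29,Visual,0.526,0.482
SEQ3_Q30,Visual,0.585,0.478
SP1_Q45/SP2_Q21/SP2_Q25,Tactile,0.600,0.355
SEQ2_Q36f/SEQ3_Q45,Tactile,0.549,0.698
SEQ3_Q37,Tactile,0.437,0.398
SEQ3_Q50,Tactile,0.666,0.149
SEQ2_Q25/SEQ3_Q62,OralTactile,0.453,0.790
SP1_Q64,OralTactile,0.439,0.852
SP1_Q65,OralTactile,0.427,0.769
SEQ3_Q71,OralTactile,0.527,0.706
SP1_Q24/SP1_Q25/SP2_Q27,Movement,0.613,0.480
SEQ2_Q27/SEQ3_Q76,Movement,0.624,0.355
SP1_Q84/SP2_Q60,Movement,0.602,0.157
SP1_Q26,Movement,0.684,0.652
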