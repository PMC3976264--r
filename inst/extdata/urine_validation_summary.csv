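mir,mean_low,mean_high,ddct,fold_change,p_value,q_value
miR21,23.51441,20.68556,-2.82885,0.14074,0.09184,0.09614
miR222,22.35019,19.48983,-2.86037,0.13770,0.09614,0.09614
miR16,23.22368,19.35065,-3.87303,0.06825,0.02804,0.08412
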