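event_type,side,n_reference,n_detected,mae_ms,sd_ms
IC,left,416,416,8.00,11.49
IC,right,416,416,5.21,14.81
TO,left,416,411,3.19,14.01
TO,right,416,411,6.81,14.53
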