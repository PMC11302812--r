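system,phase,beam_mode,mdd_mm,mean_delay_ms,sd_ms
Catalyst,beam_on,"10xFFF, 2400",7.13,297.08,14.17
Catalyst,beam_on,"6xFFF, 1200",7.26,302.50,6.67
Catalyst,beam_on,"6x, 600",7.33,305.42,5.42
Catalyst,beam_on,"10x, 400",7.41,308.75,20.00
Catalyst,beam_off,"10xFFF, 2400",2.35,97.69,1.87
Catalyst,beam_off,"6xFFF, 1200",2.33,97.07,1.87
Catalyst,beam_off,"6x, 600",2.42,100.80,2.29
Catalyst,beam_off,"10x, 400",2.29,95.20,2.29
AlignRT V6.3.226,beam_on,"10xFFF, 2400",2.04,85.09,13.43
AlignRT V6.3.226,beam_on,"6xFFF, 1200",2.12,88.39,13.98
AlignRT V6.3.226,beam_on,"6x, 600",2.28,95.04,17.09
AlignRT V6.3.226,beam_on,"10x, 400",2.40,100.00,22.37
AlignRT V6.3.226,beam_off,"10xFFF, 2400",2.92,121.80,1.40
AlignRT V6.3.226,beam_off,"6xFFF, 1200",2.96,123.41,2.32
AlignRT V6.3.226,beam_off,"6x, 600",2.94,122.50,2.02
AlignRT V6.3.226,beam_off,"10x, 400",2.88,119.78,2.20
AlignRT V7.1.1,beam_on,"10xFFF, 2400",2.24,93.34,17.41
AlignRT V7.1.1,beam_on,"6xFFF, 1200",3.04,126.55,11.08
AlignRT V7.1.1,beam_on,"6x, 600",3.10,129.10,18.11
AlignRT V7.1.1,beam_on,"10x, 400",2.99,124.44,5.09
AlignRT V7.1.1,beam_off,"10xFFF, 2400",2.86,119.33,2.31
AlignRT V7.1.1,beam_off,"6xFFF, 1200",2.90,120.67,1.63
AlignRT V7.1.1,beam_off,"6x, 600",2.88,120.00,2.11
AlignRT V7.1.1,beam_off,"10x, 400",2.85,118.67,2.31
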