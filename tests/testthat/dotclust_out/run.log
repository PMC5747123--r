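dotclust pipeline
config: {"input":null,"out_dir":"dotclust_out","labels":null,"align":{"theta":0.5,"kappa":0.3,"gap_open":1,"gap_ext":0.05,"temp":0.25,"n_samples":0,"seed":null,"free_end_gaps":false,"mismatch_score":0,"band_width":null},"cluster":{"eps":1,"min_pts":4,"xi":0.006,"minimum_only":true},"fold":{"w_gc":3,"w_au":2,"w_gu":1,"stack_bonus":1,"kT":1,"min_hairpin":3,"p_min":0.001},"n_jobs":1,"seed":1}
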