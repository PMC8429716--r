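{"version":1,"coefficients":[-9.06858006424361,3.66400910006922,1.080873194439],"cells":[{"J":2,"L":5,"df":4.07071115940413,"zero_mass":0},{"J":3,"L":5,"df":6.85716299059112,"zero_mass":0},{"J":4,"L":5,"df":10.8108234529035,"zero_mass":0},{"J":2,"L":10,"df":6.7100992599361,"zero_mass":0.0166666666666667},{"J":3,"L":10,"df":12.1598657363464,"zero_mass":0},{"J":4,"L":10,"df":19.6853277224966,"zero_mass":0}],"lambda":1,"cv_folds":10}
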