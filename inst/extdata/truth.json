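{"n_snps":8,"n_exposure":7827,"n_outcome_cases":6000,"n_outcome_controls":190000,"beta_causal":-0.1,"pleiotropy":"none","pleiotropy_mean":0,"pleiotropy_sd":0,"inside_violation":false,"target_r2":0.0265,"n_outliers":0,"outlier_shift_se":0,"maf_range":[0.1,0.45],"palindromic_frac":0,"seed":20220405,"gamma":[0.0548787031855351,0.0760738526583028,0.0487954514443377,0.159538193116832,0.0766739213890294,0.0775933577461905,0.131245798432153,0.0742561331378454],"alpha":[0,0,0,0,0,0,0,0],"Gamma":[-0.00548787031855351,-0.00760738526583028,-0.00487954514443377,-0.0159538193116832,-0.00766739213890294,-0.00775933577461905,-0.0131245798432153,-0.00742561331378454],"maf":[0.176459084032103,0.209569521050435,0.274922965432052,0.227904953388497,0.133845831244253,0.287654437788296,0.324075850553345,0.326148582471069],"outlier_rsids":[],"realized_r2":0.0265}
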