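sample_group,replicate,gene,ct
control,1,ODC,20.1
control,1,krt12.4,22.4
control,1,pou5f3.2,26.8
control,2,ODC,20.3
control,2,krt12.4,22.7
control,2,pou5f3.2,27.1
control,3,ODC,19.9
control,3,krt12.4,22.2
control,3,pou5f3.2,26.9
treated,1,ODC,20.2
treated,1,krt12.4,24.1
treated,1,pou5f3.2,25.3
treated,2,ODC,20.0
treated,2,krt12.4,23.8
treated,2,pou5f3.2,25.1
treated,3,ODC,20.4
treated,3,krt12.4,24.5
treated,3,pou5f3.2,25.6
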