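"method","band_index"
"attention_joint",2
"attention_joint",5
"attention_joint",14
"attention_joint",15
"attention_joint",16
"attention_joint",17
"attention_joint",19
"attention_joint",22
"attention_joint",27
"attention_joint",29
"attention_joint",32
"attention_joint",34
"attention_joint",36
"attention_joint",38
"attention_joint",41
"attention_joint",48
"attention_joint",49
"attention_joint",50
"attention_joint",64
"attention_joint",69
"attention_joint",70
"attention_joint",71
"attention_joint",74
"attention_joint",77
"attention_joint",78
"attention_joint",80
"attention_joint",85
"attention_joint",87
"attention_joint",91
"attention_joint",92
"attention_joint",97
"attention_joint",99
"attention_joint",100
"attention_joint",103
"attention_joint",106
"attention_joint",108
"attention_joint",110
"attention_joint",112
"attention_joint",113
"attention_joint",114
"attention_joint",118
"attention_joint",121
"attention_joint",131
"attention_joint",133
"attention_joint",136
"attention_joint",142
"attention_joint",150
"attention_joint",155
"attention_joint",157
"attention_joint",159
"attention_joint",160
"attention_joint",161
"attention_joint",162
"attention_joint",163
"attention_joint",166
"attention_joint",170
"bs_net_conv",6
"bs_net_conv",10
"bs_net_conv",12
"bs_net_conv",15
"bs_net_conv",17
"bs_net_conv",20
"bs_net_conv",23
"bs_net_conv",25
"bs_net_conv",30
"bs_net_conv",34
"bs_net_conv",36
"bs_net_conv",38
"bs_net_conv",40
"bs_net_conv",42
"bs_net_conv",43
"bs_net_conv",44
"bs_net_conv",48
"bs_net_conv",49
"bs_net_conv",56
"bs_net_conv",64
"bs_net_conv",68
"bs_net_conv",75
"bs_net_conv",77
"bs_net_conv",81
"bs_net_conv",83
"bs_net_conv",84
"bs_net_conv",85
"bs_net_conv",86
"bs_net_conv",89
"bs_net_conv",90
"bs_net_conv",92
"bs_net_conv",94
"bs_net_conv",95
"bs_net_conv",96
"bs_net_conv",101
"bs_net_conv",103
"bs_net_conv",113
"bs_net_conv",118
"bs_net_conv",122
"bs_net_conv",124
"bs_net_conv",128
"bs_net_conv",131
"bs_net_conv",134
"bs_net_conv",140
"bs_net_conv",144
"bs_net_conv",147
"bs_net_conv",153
"bs_net_conv",154
"bs_net_conv",156
"bs_net_conv",159
"bs_net_conv",161
"bs_net_conv",162
"bs_net_conv",163
"bs_net_conv",165
"bs_net_conv",170
"bs_net_conv",175
"darecnet",48
"darecnet",49
"darecnet",50
"darecnet",51
"darecnet",52
"darecnet",53
"darecnet",54
"darecnet",55
"darecnet",56
"darecnet",57
"darecnet",58
"darecnet",59
"darecnet",60
"darecnet",61
"darecnet",62
"darecnet",63
"darecnet",64
"darecnet",65
"darecnet",66
"darecnet",67
"darecnet",68
"darecnet",69
"darecnet",70
"darecnet",71
"darecnet",72
"darecnet",73
"darecnet",74
"darecnet",75
"darecnet",76
"darecnet",77
"darecnet",78
"darecnet",79
"darecnet",80
"darecnet",81
"darecnet",82
"darecnet",83
"darecnet",84
"darecnet",85
"darecnet",86
"darecnet",87
"darecnet",88
"darecnet",89
"darecnet",90
"darecnet",91
"darecnet",92
"darecnet",93
"darecnet",94
"darecnet",95
"darecnet",96
"darecnet",97
"darecnet",98
"darecnet",99
"darecnet",100
"darecnet",101
"darecnet",102
"darecnet",103
"cars_plsr",0
"cars_plsr",3
"cars_plsr",4
"cars_plsr",5
"cars_plsr",6
"cars_plsr",7
"cars_plsr",8
"cars_plsr",9
"cars_plsr",10
"cars_plsr",11
"cars_plsr",12
"cars_plsr",13
"cars_plsr",15
"cars_plsr",16
"cars_plsr",18
"cars_plsr",19
"cars_plsr",20
"cars_plsr",21
"cars_plsr",22
"cars_plsr",24
"cars_plsr",25
"cars_plsr",27
"cars_plsr",28
"cars_plsr",29
"cars_plsr",31
"cars_plsr",32
"cars_plsr",34
"cars_plsr",35
"cars_plsr",36
"cars_plsr",40
"cars_plsr",41
"cars_plsr",42
"cars_plsr",45
"cars_plsr",46
"cars_plsr",47
"cars_plsr",48
"cars_plsr",52
"cars_plsr",53
"cars_plsr",54
"cars_plsr",55
"cars_plsr",56
"cars_plsr",69
"cars_plsr",70
"cars_plsr",71
"cars_plsr",82
"cars_plsr",87
"cars_plsr",92
"cars_plsr",153
"cars_plsr",154
"cars_plsr",155
"cars_plsr",160
"cars_plsr",161
"cars_plsr",163
"cars_plsr",167
"cars_plsr",170
"cars_plsr",175
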