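group,temperature_C,time,time_unit,fa_code,percent
EG,4,0,d,C18:2n-6c,1.2
EG,4,0,d,C18:3n-6,0.57
EG,4,0,d,C18:3n-3,1.09
EG,4,0,d,C20:2n-6,0.56
EG,4,0,d,C20:3n-6,3.53
EG,4,0,d,C20:3n-3,0.24
EG,4,0,d,C20:4n-6,9.24
EG,4,0,d,C22:2n-6,0.43
EG,4,0,d,C20:5n-3,2.36
EG,4,0,d,C22:5n-3,2.56
EG,4,0,d,C22:6n-3,33.26
EG,4,0,d,PUFA,55.03
EG,4,0,d,SFA,31.57
EG,4,0,d,MUFA,13.4
EG,4,3,d,C18:2n-6c,0.8
EG,4,3,d,C18:3n-6,0.64
EG,4,3,d,C18:3n-3,1.29
EG,4,3,d,C20:2n-6,0.42
EG,4,3,d,C20:3n-6,3.49
EG,4,3,d,C20:3n-3,0.27
EG,4,3,d,C20:4n-6,7.8
EG,4,3,d,C22:2n-6,0.51
EG,4,3,d,C20:5n-3,2.32
EG,4,3,d,C22:5n-3,1.87
EG,4,3,d,C22:6n-3,33.04
EG,4,3,d,PUFA,52.44
EG,4,3,d,SFA,35.88
EG,4,3,d,MUFA,11.68
EG,4,6,d,C18:2n-6c,1.69
EG,4,6,d,C18:3n-6,0.56
EG,4,6,d,C18:3n-3,1.07
EG,4,6,d,C20:2n-6,0.26
EG,4,6,d,C20:3n-6,2.93
EG,4,6,d,C20:3n-3,0.51
EG,4,6,d,C20:4n-6,7.47
EG,4,6,d,C22:2n-6,0.47
EG,4,6,d,C20:5n-3,2.22
EG,4,6,d,C22:5n-3,2.58
EG,4,6,d,C22:6n-3,31.82
EG,4,6,d,PUFA,51.59
EG,4,6,d,SFA,37.8
EG,4,6,d,MUFA,10.62
EG,4,9,d,C18:2n-6c,1.4
EG,4,9,d,C18:3n-6,0.53
EG,4,9,d,C18:3n-3,0.96
EG,4,9,d,C20:2n-6,0.25
EG,4,9,d,C20:3n-6,3.15
EG,4,9,d,C20:3n-3,0.44
EG,4,9,d,C20:4n-6,6.53
EG,4,9,d,C22:2n-6,0.78
EG,4,9,d,C20:5n-3,2.49
EG,4,9,d,C22:5n-3,2.57
EG,4,9,d,C22:6n-3,31.69
EG,4,9,d,PUFA,50.79
EG,4,9,d,SFA,39.2
EG,4,9,d,MUFA,10.01
CG,4,0,d,C18:2n-6c,0.83
CG,4,0,d,C18:3n-6,0.37
CG,4,0,d,C18:3n-3,0.95
CG,4,0,d,C20:2n-6,0.47
CG,4,0,d,C20:3n-6,3.09
CG,4,0,d,C20:3n-3,0.3
CG,4,0,d,C20:4n-6,8.89
CG,4,0,d,C22:2n-6,0.34
CG,4,0,d,C20:5n-3,2.17
CG,4,0,d,C22:5n-3,2.65
CG,4,0,d,C22:6n-3,34.22
CG,4,0,d,PUFA,54.28
CG,4,0,d,SFA,31.99
CG,4,0,d,MUFA,13.73
CG,4,3,d,C18:2n-6c,0.76
CG,4,3,d,C18:3n-6,0.41
CG,4,3,d,C18:3n-3,0.87
CG,4,3,d,C20:2n-6,0.24
CG,4,3,d,C20:3n-6,3.46
CG,4,3,d,C20:3n-3,0.39
CG,4,3,d,C20:4n-6,6.73
CG,4,3,d,C22:2n-6,0.71
CG,4,3,d,C20:5n-3,2.72
CG,4,3,d,C22:5n-3,2.72
CG,4,3,d,C22:6n-3,32.01
CG,4,3,d,PUFA,51.01
CG,4,3,d,SFA,37.29
CG,4,3,d,MUFA,11.7
CG,4,6,d,C18:2n-6c,0.87
CG,4,6,d,C18:3n-6,0.37
CG,4,6,d,C18:3n-3,0.92
CG,4,6,d,C20:2n-6,0.29
CG,4,6,d,C20:3n-6,2.91
CG,4,6,d,C20:3n-3,0.42
CG,4,6,d,C20:4n-6,7.82
CG,4,6,d,C22:2n-6,0.61
CG,4,6,d,C20:5n-3,2.35
CG,4,6,d,C22:5n-3,2.69
CG,4,6,d,C22:6n-3,30.62
CG,4,6,d,PUFA,49.86
CG,4,6,d,SFA,40.09
CG,4,6,d,MUFA,10.05
CG,4,9,d,C18:2n-6c,1.04
CG,4,9,d,C18:3n-6,0.42
CG,4,9,d,C18:3n-3,0.92
CG,4,9,d,C20:2n-6,0.4
CG,4,9,d,C20:3n-6,3.43
CG,4,9,d,C20:3n-3,0.45
CG,4,9,d,C20:4n-6,5.74
CG,4,9,d,C22:2n-6,0.55
CG,4,9,d,C20:5n-3,2.12
CG,4,9,d,C22:5n-3,2.53
CG,4,9,d,C22:6n-3,29.12
CG,4,9,d,PUFA,46.73
CG,4,9,d,SFA,44.04
CG,4,9,d,MUFA,9.23
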