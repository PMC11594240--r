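group,temperature_C,time,time_unit,fa_code,percent
EG,25,0,h,C18:2n-6c,1.2
EG,25,0,h,C18:3n-6,0.57
EG,25,0,h,C18:3n-3,1.09
EG,25,0,h,C20:2n-6,0.56
EG,25,0,h,C20:3n-6,3.53
EG,25,0,h,C20:3n-3,0.24
EG,25,0,h,C20:4n-6,9.24
EG,25,0,h,C22:2n-6,0.43
EG,25,0,h,C20:5n-3,2.36
EG,25,0,h,C22:5n-3,2.56
EG,25,0,h,C22:6n-3,33.26
EG,25,0,h,PUFA,55.03
EG,25,0,h,SFA,31.57
EG,25,0,h,MUFA,13.4
EG,25,12,h,C18:2n-6c,1.2
EG,25,12,h,C18:3n-6,0.61
EG,25,12,h,C18:3n-3,1.74
EG,25,12,h,C20:2n-6,0.23
EG,25,12,h,C20:3n-6,3.42
EG,25,12,h,C20:3n-3,0.58
EG,25,12,h,C20:4n-6,8.5
EG,25,12,h,C22:2n-6,0.93
EG,25,12,h,C20:5n-3,1.93
EG,25,12,h,C22:5n-3,2.56
EG,25,12,h,C22:6n-3,31.07
EG,25,12,h,PUFA,52.78
EG,25,12,h,SFA,34.08
EG,25,12,h,MUFA,13.13
EG,25,24,h,C18:2n-6c,1.46
EG,25,24,h,C18:3n-6,0.59
EG,25,24,h,C18:3n-3,1.82
EG,25,24,h,C20:2n-6,0.21
EG,25,24,h,C20:3n-6,3.21
EG,25,24,h,C20:3n-3,0.64
EG,25,24,h,C20:4n-6,8.03
EG,25,24,h,C22:2n-6,0.78
EG,25,24,h,C20:5n-3,2.01
EG,25,24,h,C22:5n-3,2.2
EG,25,24,h,C22:6n-3,28.99
EG,25,24,h,PUFA,49.95
EG,25,24,h,SFA,37.37
EG,25,24,h,MUFA,12.68
EG,25,36,h,C18:2n-6c,1.41
EG,25,36,h,C18:3n-6,0.56
EG,25,36,h,C18:3n-3,1.79
EG,25,36,h,C20:2n-6,0.24
EG,25,36,h,C20:3n-6,3.13
EG,25,36,h,C20:3n-3,0.57
EG,25,36,h,C20:4n-6,7.56
EG,25,36,h,C22:2n-6,0.9
EG,25,36,h,C20:5n-3,1.82
EG,25,36,h,C22:5n-3,2.29
EG,25,36,h,C22:6n-3,28.11
EG,25,36,h,PUFA,48.4
EG,25,36,h,SFA,39.54
EG,25,36,h,MUFA,12.06
EG,25,48,h,C18:2n-6c,1.64
EG,25,48,h,C18:3n-6,0.76
EG,25,48,h,C18:3n-3,1.8
EG,25,48,h,C20:2n-6,0.26
EG,25,48,h,C20:3n-6,3.05
EG,25,48,h,C20:3n-3,0.6
EG,25,48,h,C20:4n-6,6.93
EG,25,48,h,C22:2n-6,0.72
EG,25,48,h,C20:5n-3,1.65
EG,25,48,h,C22:5n-3,1.84
EG,25,48,h,C22:6n-3,25.3
EG,25,48,h,PUFA,44.54
EG,25,48,h,SFA,43.24
EG,25,48,h,MUFA,12.22
CG,25,0,h,C18:2n-6c,0.83
CG,25,0,h,C18:3n-6,0.37
CG,25,0,h,C18:3n-3,0.95
CG,25,0,h,C20:2n-6,0.47
CG,25,0,h,C20:3n-6,3.09
CG,25,0,h,C20:3n-3,0.3
CG,25,0,h,C20:4n-6,8.89
CG,25,0,h,C22:2n-6,0.34
CG,25,0,h,C20:5n-3,2.17
CG,25,0,h,C22:5n-3,2.65
CG,25,0,h,C22:6n-3,34.22
CG,25,0,h,PUFA,54.28
CG,25,0,h,SFA,31.99
CG,25,0,h,MUFA,13.73
CG,25,12,h,C18:2n-6c,1.05
CG,25,12,h,C18:3n-6,0.56
CG,25,12,h,C18:3n-3,1.25
CG,25,12,h,C20:2n-6,0.24
CG,25,12,h,C20:3n-6,2.59
CG,25,12,h,C20:3n-3,0.43
CG,25,12,h,C20:4n-6,8.65
CG,25,12,h,C22:2n-6,0.8
CG,25,12,h,C20:5n-3,2.25
CG,25,12,h,C22:5n-3,2.61
CG,25,12,h,C22:6n-3,31.7
CG,25,12,h,PUFA,52.14
CG,25,12,h,SFA,35.99
CG,25,12,h,MUFA,11.86
CG,25,24,h,C18:2n-6c,1.22
CG,25,24,h,C18:3n-6,0.56
CG,25,24,h,C18:3n-3,1.43
CG,25,24,h,C20:2n-6,0.24
CG,25,24,h,C20:3n-6,2.15
CG,25,24,h,C20:3n-3,0.44
CG,25,24,h,C20:4n-6,7.58
CG,25,24,h,C22:2n-6,0.45
CG,25,24,h,C20:5n-3,1.98
CG,25,24,h,C22:5n-3,2.65
CG,25,24,h,C22:6n-3,29.74
CG,25,24,h,PUFA,48.45
CG,25,24,h,SFA,39.84
CG,25,24,h,MUFA,11.7
CG,25,36,h,C18:2n-6c,1.05
CG,25,36,h,C18:3n-6,0.58
CG,25,36,h,C18:3n-3,1.39
CG,25,36,h,C20:2n-6,0.4
CG,25,36,h,C20:3n-6,1.95
CG,25,36,h,C20:3n-3,0.4
CG,25,36,h,C20:4n-6,7.56
CG,25,36,h,C22:2n-6,0.6
CG,25,36,h,C20:5n-3,1.89
CG,25,36,h,C22:5n-3,2.57
CG,25,36,h,C22:6n-3,29.14
CG,25,36,h,PUFA,47.54
CG,25,36,h,SFA,41.28
CG,25,36,h,MUFA,11.19
CG,25,48,h,C18:2n-6c,1.05
CG,25,48,h,C18:3n-6,0.69
CG,25,48,h,C18:3n-3,1.33
CG,25,48,h,C20:2n-6,0.42
CG,25,48,h,C20:3n-6,1.91
CG,25,48,h,C20:3n-3,0.49
CG,25,48,h,C20:4n-6,6.22
CG,25,48,h,C22:2n-6,0.46
CG,25,48,h,C20:5n-3,1.42
CG,25,48,h,C22:5n-3,2.3
CG,25,48,h,C22:6n-3,26.42
CG,25,48,h,PUFA,42.73
CG,25,48,h,SFA,46.36
CG,25,48,h,MUFA,10.91
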