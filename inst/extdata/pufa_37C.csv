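group,temperature_C,time,time_unit,fa_code,percent
EG,37,0,h,C18:2n-6c,1.2
EG,37,0,h,C18:3n-6,0.57
EG,37,0,h,C18:3n-3,1.09
EG,37,0,h,C20:2n-6,0.56
EG,37,0,h,C20:3n-6,3.53
EG,37,0,h,C20:3n-3,0.24
EG,37,0,h,C20:4n-6,9.24
EG,37,0,h,C22:2n-6,0.43
EG,37,0,h,C20:5n-3,2.36
EG,37,0,h,C22:5n-3,2.56
EG,37,0,h,C22:6n-3,33.26
EG,37,0,h,PUFA,55.03
EG,37,0,h,SFA,31.99
EG,37,0,h,MUFA,13.73
EG,37,1,h,C18:2n-6c,1.21
EG,37,1,h,C18:3n-6,0.42
EG,37,1,h,C18:3n-3,0.53
EG,37,1,h,C20:2n-6,0.35
EG,37,1,h,C20:3n-6,4.21
EG,37,1,h,C20:3n-3,0.28
EG,37,1,h,C20:4n-6,7.42
EG,37,1,h,C22:2n-6,0.79
EG,37,1,h,C20:5n-3,2.96
EG,37,1,h,C22:5n-3,2.95
EG,37,1,h,C22:6n-3,32.54
EG,37,1,h,PUFA,53.68
EG,37,1,h,SFA,34.46
EG,37,1,h,MUFA,12.31
EG,37,2,h,C18:2n-6c,0.93
EG,37,2,h,C18:3n-6,0.58
EG,37,2,h,C18:3n-3,1.63
EG,37,2,h,C20:2n-6,0.24
EG,37,2,h,C20:3n-6,3.35
EG,37,2,h,C20:3n-3,0.51
EG,37,2,h,C20:4n-6,7.61
EG,37,2,h,C22:2n-6,0.28
EG,37,2,h,C20:5n-3,2.33
EG,37,2,h,C22:5n-3,2.61
EG,37,2,h,C22:6n-3,31.72
EG,37,2,h,PUFA,51.79
EG,37,2,h,SFA,35.53
EG,37,2,h,MUFA,14.64
EG,37,3,h,C18:2n-6c,1.37
EG,37,3,h,C18:3n-6,0.71
EG,37,3,h,C18:3n-3,1.76
EG,37,3,h,C20:2n-6,0.33
EG,37,3,h,C20:3n-6,3.74
EG,37,3,h,C20:3n-3,0.46
EG,37,3,h,C20:4n-6,7.11
EG,37,3,h,C22:2n-6,0.42
EG,37,3,h,C20:5n-3,1.73
EG,37,3,h,C22:5n-3,2.2
EG,37,3,h,C22:6n-3,30.26
EG,37,3,h,PUFA,50.08
EG,37,3,h,SFA,37.9
EG,37,3,h,MUFA,13.73
EG,37,4,h,C18:2n-6c,1.36
EG,37,4,h,C18:3n-6,0.62
EG,37,4,h,C18:3n-3,1.56
EG,37,4,h,C20:2n-6,0.27
EG,37,4,h,C20:3n-6,3.6
EG,37,4,h,C20:3n-3,0.37
EG,37,4,h,C20:4n-6,6.2
EG,37,4,h,C22:2n-6,0.38
EG,37,4,h,C20:5n-3,2.12
EG,37,4,h,C22:5n-3,2.27
EG,37,4,h,C22:6n-3,29.1
EG,37,4,h,PUFA,47.84
EG,37,4,h,SFA,41.11
EG,37,4,h,MUFA,13.63
EG,37,5,h,C18:2n-6c,1.21
EG,37,5,h,C18:3n-6,0.35
EG,37,5,h,C18:3n-3,1.46
EG,37,5,h,C20:2n-6,0.25
EG,37,5,h,C20:3n-6,3.71
EG,37,5,h,C20:3n-3,0.3
EG,37,5,h,C20:4n-6,6.03
EG,37,5,h,C22:2n-6,0.45
EG,37,5,h,C20:5n-3,1.46
EG,37,5,h,C22:5n-3,2.08
EG,37,5,h,C22:6n-3,27.71
EG,37,5,h,PUFA,45.01
EG,37,5,h,SFA,45.84
EG,37,5,h,MUFA,12.87
EG,37,6,h,C18:2n-6c,1.5
EG,37,6,h,C18:3n-6,0.51
EG,37,6,h,C18:3n-3,0.67
EG,37,6,h,C20:2n-6,0.22
EG,37,6,h,C20:3n-6,2.77
EG,37,6,h,C20:3n-3,0.36
EG,37,6,h,C20:4n-6,6.22
EG,37,6,h,C22:2n-6,0.38
EG,37,6,h,C20:5n-3,1.71
EG,37,6,h,C22:5n-3,2.22
EG,37,6,h,C22:6n-3,26.84
EG,37,6,h,PUFA,43.41
EG,37,6,h,SFA,49.75
EG,37,6,h,MUFA,11.15
CG,37,0,h,C18:2n-6c,0.83
CG,37,0,h,C18:3n-6,0.37
CG,37,0,h,C18:3n-3,0.95
CG,37,0,h,C20:2n-6,0.47
CG,37,0,h,C20:3n-6,3.09
CG,37,0,h,C20:3n-3,0.3
CG,37,0,h,C20:4n-6,8.89
CG,37,0,h,C22:2n-6,0.34
CG,37,0,h,C20:5n-3,2.17
CG,37,0,h,C22:5n-3,2.65
CG,37,0,h,C22:6n-3,34.22
CG,37,0,h,PUFA,54.28
CG,37,0,h,SFA,31.99
CG,37,0,h,MUFA,13.73
CG,37,1,h,C18:2n-6c,1.19
CG,37,1,h,C18:3n-6,0.41
CG,37,1,h,C18:3n-3,0.59
CG,37,1,h,C20:2n-6,0.36
CG,37,1,h,C20:3n-6,4.53
CG,37,1,h,C20:3n-3,0.24
CG,37,1,h,C20:4n-6,7.29
CG,37,1,h,C22:2n-6,0.56
CG,37,1,h,C20:5n-3,2.85
CG,37,1,h,C22:5n-3,2.21
CG,37,1,h,C22:6n-3,33.01
CG,37,1,h,PUFA,53.23
CG,37,1,h,SFA,34.46
CG,37,1,h,MUFA,12.31
CG,37,2,h,C18:2n-6c,0.81
CG,37,2,h,C18:3n-6,0.53
CG,37,2,h,C18:3n-3,1.53
CG,37,2,h,C20:2n-6,0.26
CG,37,2,h,C20:3n-6,3.08
CG,37,2,h,C20:3n-3,0.59
CG,37,2,h,C20:4n-6,7.85
CG,37,2,h,C22:2n-6,0.3
CG,37,2,h,C20:5n-3,2.33
CG,37,2,h,C22:5n-3,2.17
CG,37,2,h,C22:6n-3,30.37
CG,37,2,h,PUFA,49.83
CG,37,2,h,SFA,35.53
CG,37,2,h,MUFA,14.64
CG,37,3,h,C18:2n-6c,0.9
CG,37,3,h,C18:3n-6,0.57
CG,37,3,h,C18:3n-3,1.74
CG,37,3,h,C20:2n-6,0.27
CG,37,3,h,C20:3n-6,3.24
CG,37,3,h,C20:3n-3,0.38
CG,37,3,h,C20:4n-6,7.66
CG,37,3,h,C22:2n-6,0.64
CG,37,3,h,C20:5n-3,2.02
CG,37,3,h,C22:5n-3,2.6
CG,37,3,h,C22:6n-3,28.35
CG,37,3,h,PUFA,48.37
CG,37,3,h,SFA,37.9
CG,37,3,h,MUFA,13.73
CG,37,4,h,C18:2n-6c,0.84
CG,37,4,h,C18:3n-6,0.52
CG,37,4,h,C18:3n-3,1.3
CG,37,4,h,C20:2n-6,0.26
CG,37,4,h,C20:3n-6,3.18
CG,37,4,h,C20:3n-3,0.4
CG,37,4,h,C20:4n-6,6.96
CG,37,4,h,C22:2n-6,0.48
CG,37,4,h,C20:5n-3,1.99
CG,37,4,h,C22:5n-3,2.34
CG,37,4,h,C22:6n-3,26.98
CG,37,4,h,PUFA,45.26
CG,37,4,h,SFA,41.11
CG,37,4,h,MUFA,13.63
CG,37,5,h,C18:2n-6c,0.89
CG,37,5,h,C18:3n-6,0.45
CG,37,5,h,C18:3n-3,1.27
CG,37,5,h,C20:2n-6,0.27
CG,37,5,h,C20:3n-6,3.04
CG,37,5,h,C20:3n-3,0.45
CG,37,5,h,C20:4n-6,6.1
CG,37,5,h,C22:2n-6,0.37
CG,37,5,h,C20:5n-3,1.85
CG,37,5,h,C22:5n-3,2.17
CG,37,5,h,C22:6n-3,24.44
CG,37,5,h,PUFA,41.29
CG,37,5,h,SFA,45.84
CG,37,5,h,MUFA,12.87
CG,37,6,h,C18:2n-6c,0.74
CG,37,6,h,C18:3n-6,0.44
CG,37,6,h,C18:3n-3,1.14
CG,37,6,h,C20:2n-6,0.24
CG,37,6,h,C20:3n-6,2.56
CG,37,6,h,C20:3n-3,0.28
CG,37,6,h,C20:4n-6,6.86
CG,37,6,h,C22:2n-6,0.28
CG,37,6,h,C20:5n-3,1.72
CG,37,6,h,C22:5n-3,2.38
CG,37,6,h,C22:6n-3,22.46
CG,37,6,h,PUFA,39.1
CG,37,6,h,SFA,49.75
CG,37,6,h,MUFA,11.15
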