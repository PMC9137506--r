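variable,group,n,mean,sd
age_years,aud,30,41.42,7.32
age_years,control,30,27.44,4.74
education_years,aud,30,11.93,2.35
education_years,control,30,15.77,1.87
alcohol_onset_age_regular_use,aud,30,15.77,2.58
alcohol_onset_age_regular_use,control,12,20.50,3.80
alcohol_quantity_per_day_heavy_use,aud,30,11,7.66
alcohol_quantity_per_day_heavy_use,control,12,3,1.60
alcohol_frequency_per_month_heavy_use,aud,30,20,9.01
alcohol_frequency_per_month_heavy_use,control,12,4,4.09
alcohol_quantity_per_day_last6mo,aud,30,3,6.61
alcohol_quantity_per_day_last6mo,control,18,3,1.98
alcohol_frequency_per_month_last6mo,aud,30,4,8.02
alcohol_frequency_per_month_last6mo,control,18,3,3.62
abstinence_length_days,aud,30,672.93,844.94
abstinence_length_days,control,18,57,149.76
tobacco_quantity_per_day_last6mo,aud,20,10,5.80
tobacco_quantity_per_day_last6mo,control,6,2,1.63
tobacco_frequency_per_month_last6mo,aud,20,28,4.83
tobacco_frequency_per_month_last6mo,control,6,14,13.82
marijuana_frequency_last6mo,aud,10,99,91.38
marijuana_frequency_last6mo,control,4,19,27.61
nogo_accuracy_percent,aud,30,85.21,15.84
nogo_accuracy_percent,control,30,94.42,11.85
go_accuracy_percent,aud,30,91.25,9.44
go_accuracy_percent,control,30,88.83,8.03
reaction_time_ms,aud,30,349.85,31.15
reaction_time_ms,control,30,324.47,32.27
bis11_nonplanning,aud,28,24.57,5.25
bis11_nonplanning,control,30,19.80,4.61
bis11_motor,aud,27,25.15,5.24
bis11_motor,control,30,19.30,3.28
bis11_attentional,aud,28,15.79,4.13
bis11_attentional,control,30,12.57,3.19
bis11_total,aud,27,65.44,11.51
bis11_total,control,30,51.67,8.60
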