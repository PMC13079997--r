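statistic,sex,count,denominator,printed_pct
participants,male,127269,NA,NA
participants,female,170194,NA,NA
participants,total,297463,NA,NA
current_smokers,male,15561,127269,12.2
current_smokers,female,14510,170194,8.5
current_smokers,total,30071,297463,10.1
cvd_events_10y,male,5633,127269,4.4
cvd_events_10y,female,3286,170194,1.9
cvd_events_10y,total,8919,297463,3.0
fatal_cvd_events,male,1140,5633,20.2
fatal_cvd_events,female,514,3286,15.6
fatal_cvd_events,total,1654,8919,18.5
primary_cause_events,male,4312,5633,76.5
primary_cause_events,female,2176,3286,66.2
primary_cause_events,total,6488,8919,72.7
noncvd_deaths_10y,male,4078,127269,3.2
noncvd_deaths_10y,female,3945,170194,2.3
noncvd_deaths_10y,total,8023,297463,2.7
lost_to_followup,male,2649,127269,2.1
lost_to_followup,female,3597,170194,2.1
lost_to_followup,total,6246,297463,2.1
ltfu_welsh_record_end,male,2337,2649,88.2
ltfu_welsh_record_end,female,3237,3597,90.0
ltfu_welsh_record_end,total,5574,6246,89.2
ltfu_other_reason,male,312,2649,11.8
ltfu_other_reason,female,360,3597,10.0
ltfu_other_reason,total,672,6246,10.8
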