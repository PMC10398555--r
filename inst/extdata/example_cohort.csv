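id,age_months,sex,q1,q2,q3,q4,q5,q6,q7,device_id,ip_address,repeat_first,repeat_second,quality,excluded_condition,reference,aware
C001,8.5,male,yes,yes,yes,yes,yes,yes,no,d01,10.0.0.1,a,a,good,no,yes,no
C002,8.5,male,yes,yes,yes,yes,yes,yes,no,d01,10.0.0.1,a,a,good,no,yes,no
C003,4.0,female,no,yes,no,yes,no,yes,no,d03,10.0.0.3,b,b,good,no,yes,yes
C004,12.2,female,yes,no,yes,no,no,no,no,d04,10.0.0.4,a,a,good,no,no,no
C005,25.0,male,no,yes,no,yes,no,yes,no,d05,10.0.0.5,a,a,good,no,yes,no
C006,6.1,male,no,no,no,no,no,no,yes,d06,10.0.0.6,c,c,good,no,yes,no
C007,18.0,female,no,yes,yes,no,no,yes,no,d07,10.0.0.7,a,a,good,no,no,no
C008,9.9,male,no,yes,no,yes,no,yes,no,d08,10.0.0.8,a,a,poor,no,yes,no
C009,3.2,female,yes,yes,yes,no,yes,yes,no,d09,10.0.0.9,b,b,good,no,no,no
C010,14.5,male,no,yes,no,yes,yes,yes,no,d10,10.0.0.10,a,a,good,no,yes,no
C011,22.0,female,no,no,yes,no,no,yes,no,d11,10.0.0.11,a,a,good,no,no,no
C012,7.7,male,no,yes,no,yes,no,no,no,d12,10.0.0.12,c,c,good,no,yes,no
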