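drug_name,antibody_type,ir_cases,reports,adcc_status,target,ror_printed,ci_low_printed,ci_high_printed,signal_printed
blinatumomab,mouse,59,244,negative,anti-CD19xCD3,17.91,13.31,24.10,TRUE
brentuximab vedotin,chimeric,5,1295,negative,anti-CD30,0.21,0.09,0.50,FALSE
cetuximab,chimeric,591,4799,positive,anti-EGFR,10.99,9.90,12.19,TRUE
isatuximab,chimeric,9,169,positive,anti-CD38,3.07,1.57,6.02,TRUE
rituximab,chimeric,64,5958,positive,anti-CD20,0.57,0.45,0.74,FALSE
alemtuzumab,humanized,4,57,positive,anti-CD52,4.11,1.49,11.37,TRUE
atezolizumab,humanized,33,3894,negative,anti-PD-L1,0.45,0.32,0.64,FALSE
bevacizumab,humanized,53,19237,negative,anti-VEGF,0.12,0.09,0.16,FALSE
elotuzumab,humanized,12,807,positive,anti-SLAMF7,0.82,0.46,1.45,FALSE
gemtuzumab ozogamicin,humanized,7,1794,negative,anti-CD33,0.21,0.10,0.44,FALSE
inotuzumab ozogamicin,humanized,3,99,negative,anti-CD22,1.70,0.54,5.37,FALSE
mogamulizumab,humanized,44,1011,positive,anti-CCR4,2.51,1.85,3.41,TRUE
obinutuzumab,humanized,39,421,positive,anti-CD20,5.65,4.05,7.89,TRUE
pembrolizumab,humanized,46,11716,negative,anti-PD-1,0.19,0.14,0.26,FALSE
pertuzumab,humanized,96,1179,positive,anti-HER2,5.04,4.07,6.24,TRUE
polatuzumab vedotin,humanized,1,329,positive,anti-CD79b,0.17,0.02,1.18,FALSE
trastuzumab,humanized,155,3568,positive,anti-HER2,2.61,2.21,3.09,TRUE
trastuzumab emtansine,humanized,5,616,positive,anti-HER2,0.44,0.18,1.07,FALSE
avelumab,fully_human,25,278,positive,anti-PD-L1,5.44,3.59,8.22,TRUE
daratumumab,fully_human,42,916,positive,anti-CD38,2.65,1.94,3.63,TRUE
durvalumab,fully_human,9,2851,negative,anti-PD-L1,0.17,0.09,0.32,FALSE
ipilimumab,fully_human,55,9351,positive,anti-CTLA-4,0.30,0.23,0.39,FALSE
nivolumab,fully_human,142,18246,negative,anti-PD-1,0.38,0.32,0.45,FALSE
panitumumab,fully_human,36,2724,negative,anti-EGFR,0.72,0.52,1.01,FALSE
ramucirumab,fully_human,57,3563,negative,anti-VEGFR2,0.88,0.67,1.15,FALSE
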