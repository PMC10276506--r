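category,component,prefix
mental illness,depression,296.2
mental illness,depression,296.3
mental illness,depression,300.4
mental illness,depression,311
mental illness,anxiety,300.0
mental illness,anxiety,300.2
mental illness,PTSD,309.81
mental illness,bipolar,296.0
mental illness,bipolar,296.1
mental illness,bipolar,296.4
mental illness,bipolar,296.5
mental illness,bipolar,296.6
mental illness,bipolar,296.7
mental illness,bipolar,296.80
mental illness,bipolar,296.89
mental illness,schizophrenia,295
substance use,alcohol use disorder/poisoning,303
substance use,alcohol use disorder/poisoning,305.0
substance use,alcohol use disorder/poisoning,980.0
substance use,alcohol use disorder/poisoning,E860.0
substance use,alcohol use disorder/poisoning,E860.1
substance use,drug use disorder/poisoning,304
substance use,drug use disorder/poisoning,305.2
substance use,drug use disorder/poisoning,305.3
substance use,drug use disorder/poisoning,305.4
substance use,drug use disorder/poisoning,305.5
substance use,drug use disorder/poisoning,305.6
substance use,drug use disorder/poisoning,305.7
substance use,drug use disorder/poisoning,965
substance use,drug use disorder/poisoning,E850
substance use,opioid use disorder/poisoning,304.0
substance use,opioid use disorder/poisoning,304.7
substance use,opioid use disorder/poisoning,305.5
substance use,opioid use disorder/poisoning,965.0
substance use,opioid use disorder/poisoning,E850.0
substance use,opioid use disorder/poisoning,E850.1
substance use,opioid use disorder/poisoning,E850.2
substance use,sedative/hypnotic/anxiolytic use disorder/poisoning,304.1
substance use,sedative/hypnotic/anxiolytic use disorder/poisoning,305.4
substance use,sedative/hypnotic/anxiolytic use disorder/poisoning,967
substance use,sedative/hypnotic/anxiolytic use disorder/poisoning,E851
substance use,sedative/hypnotic/anxiolytic use disorder/poisoning,E852
substance use,sedative/hypnotic/anxiolytic use disorder/poisoning,E853
substance use,cannabis use disorder,304.3
substance use,cannabis use disorder,305.2
substance use,stimulant use disorder/poisoning,304.2
substance use,stimulant use disorder/poisoning,304.4
substance use,stimulant use disorder/poisoning,305.6
substance use,stimulant use disorder/poisoning,305.7
substance use,stimulant use disorder/poisoning,969.7
substance use,stimulant use disorder/poisoning,E854.2
pain,rheumatoid arthritis/osteoarthritis,714
pain,rheumatoid arthritis/osteoarthritis,715
pain,migraine/chronic headache,346
pain,migraine/chronic headache,339
pain,migraine/chronic headache,784.0
pain,fibromyalgia/chronic pain/fatigue,729.1
pain,fibromyalgia/chronic pain/fatigue,338.2
pain,fibromyalgia/chronic pain/fatigue,338.4
pain,fibromyalgia/chronic pain/fatigue,780.71
chronic disease,acute MI,410
chronic disease,heart failure,428
chronic disease,hypertension,401
chronic disease,hypertension,402
chronic disease,hypertension,403
chronic disease,hypertension,404
chronic disease,hypertension,405
chronic disease,stroke/transient ischemic attack,430
chronic disease,stroke/transient ischemic attack,431
chronic disease,stroke/transient ischemic attack,433
chronic disease,stroke/transient ischemic attack,434
chronic disease,stroke/transient ischemic attack,435
chronic disease,stroke/transient ischemic attack,436
chronic disease,asthma,493
chronic disease,COPD,490
chronic disease,COPD,491
chronic disease,COPD,492
chronic disease,COPD,496
chronic disease,diabetes,250
chronic disease,TBI,850
chronic disease,TBI,851
chronic disease,TBI,852
chronic disease,TBI,853
chronic disease,TBI,854
chronic disease,epilepsy,345
chronic disease,cancer,153
chronic disease,cancer,154
chronic disease,cancer,162
chronic disease,cancer,174
chronic disease,cancer,182
chronic disease,cancer,185
assault,assault,E960
assault,assault,E961
assault,assault,E962
assault,assault,E963
assault,assault,E965
assault,assault,E966
assault,assault,E967
assault,assault,E968
suicidal ideation/attempt,suicidal ideation,V62.84
suicidal ideation/attempt,suicide attempt,E950
suicidal ideation/attempt,suicide attempt,E951
suicidal ideation/attempt,suicide attempt,E952
suicidal ideation/attempt,suicide attempt,E953
suicidal ideation/attempt,suicide attempt,E954
suicidal ideation/attempt,suicide attempt,E955
suicidal ideation/attempt,suicide attempt,E956
suicidal ideation/attempt,suicide attempt,E957
suicidal ideation/attempt,suicide attempt,E958
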