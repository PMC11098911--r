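{
  "catatonia": ["catatonia"],
  "malignant catatonia": ["malignant catatonia"],
  "withdrawal catatonia": ["withdrawal catatonia"],
  "automatism": ["automatism"],
  "echolalia": ["echolalia"],
  "echopraxia": ["echopraxia"],
  "posturing": ["posturing"],
  "waxy flexibility": ["waxy flexibility"],
  "agitation": ["agitation"],
  "eating disorder": ["eating disorder"],
  "speech disorder": ["speech disorder"],
  "stereotypy": ["stereotypy"],
  "social avoidant behaviour": ["social avoidant behaviour"]
}
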