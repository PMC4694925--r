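# Example configuration for the ambiguous-cue inference task.
# Every key under `params` maps to an argument of sornParams().
params:
  nExc: 200
  pEE: 0.1
  nInput: 10
  wIn: 0.5
  etaStdp: 0.001
  etaIp: 0.001
  hIp: 0.1
  epsIp: 0.01
  tEMax: 0.5
  tIMax: 1.0
  pruneZeroWeights: true
  structuralRate: 0.1
  structuralInit: 0.001
  noiseSd: 0.0
phaseLengths:
  plastic: 50000
  train: 20000
  test: 50000
preset: inference
priorA: 0.33
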