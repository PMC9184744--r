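# Demo run: synthetic periodic + control segments, a three-bait co-IP
# simulation, and a neurite scene. All sizes kept small for a quick demo.
seed: 1
out: mps-demo
periodicity:
  simulate:
    nSegments: 20
control:
  simulate:
    nSegments: 20
twocolor:
  simulate:
    nSegments: 20
    channelPhaseOffset: 0.5
coip:
  simulate:
    nProteins: 40
    nTrueInteractors: 8
neurite:
  simulate:
    imageShape: [256, 256]
    nAxons: 5
    nDendrites: 4
  radius: 266
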