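# COPD dose-selection trial with a binary final outcome: failure rates per
# arm, normal early outcome, best-two selection.
design: treatsel
n.stage1: 100
n.stage2: 300
effect.early: [0.0, 0.68, 0.82, 0.95, 0.91]
effect.final: [0.50, 0.45, 0.45, 0.40, 0.40]
outcome.early: "N"
outcome.final: "B"
corr: 0.4
select: 2
ptest: [3, 4]
method: invnorm
level: 0.025
nsim: 10000
seed: 145514
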