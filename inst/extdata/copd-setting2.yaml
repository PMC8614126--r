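# COPD dose-selection trial with threshold selection: all doses whose early
# z statistic reaches 3 continue; futility stop when none do.
design: treatsel
n.stage1: 40
n.stage2: 400
effect.early: [0.0, 0.68, 0.82, 0.95, 0.91]
effect.final: [0.0, 0.13, 0.17, 0.23, 0.20]
outcome.early: "N"
outcome.final: "N"
corr: 0.4
select: 6
thresh: 3
ptest: [3, 4]
method: invnorm
level: 0.025
nsim: 10000
seed: 145514
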