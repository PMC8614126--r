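# Multi-arm COPD dose-selection trial: four indacaterol doses vs placebo,
# normal early (trough FEV1 at 15 days) and final (% days of poor control)
# outcomes, always selecting the best two doses at the interim.
design: treatsel
n.stage1: 100
n.stage2: 300
effect.early: [0.0, 0.68, 0.82, 0.95, 0.91]
effect.final: [0.0, 0.13, 0.17, 0.23, 0.20]
outcome.early: "N"
outcome.final: "N"
corr: 0.4
select: 2
ptest: [3, 4]
method: invnorm
level: 0.025
nsim: 10000
seed: 145514
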