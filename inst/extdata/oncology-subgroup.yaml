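# Oncology enrichment trial: time-to-event early and final outcomes with
# hazard ratio 0.6 in a prevalence-0.3 subgroup and 0.9 in the full
# population; futility selection rule with both limits 0; Spiessens-Debois
# combination-test analysis; stage-2 enrichment to 200/arm when continuing
# in the subgroup only.
design: subpop
n.stage1: 100
n.enrich: 200
n.stage2: 300
effect.early: [0.6, 0.9]
effect.final: [0.6, 0.9]
outcome.early: "T"
outcome.final: "T"
sprev: 0.3
corr: 0.5
select: futility
selim: [0.0, 0.0]
method: CT-SD
level: 0.025
nsim: 10000
seed: 1234
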