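# Full robustness protocol: baseline plus the five perturbations on the
# standard 1,000-bin Poisson chromosome, five replicate seeds. Emits one
# report_<kind>.json per arm (5 perturbations + 1 baseline). Takes ~10 min
# on one CPU; shrink n_bins / perturb_seeds for a smoke run.
task = perturbation_suite
seed = 1
n_bins = 1000
n_segments = 10
min_len = 20
max_len = 50
noise = poisson
dim = 64
hidden = 64
dropout = 0.5
gcn_epochs = 150
embed_epochs = 2
lr = 0.01
perturb_seeds = 1,2,3,4,5
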