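# Small end-to-end demo: simulate one chromosome and run the node2vec + GCN
# pipeline. Sized to finish in a few seconds; raise n_bins to 1000 and
# embed_epochs to 5 for the full-scale run.
task = gcn
seed = 1
n_bins = 200
n_segments = 6
min_len = 10
max_len = 20
noise = poisson
dim = 64
hidden = 64
dropout = 0.5
gcn_epochs = 80
embed_epochs = 2
lr = 0.01
head = sigmoid
train_fraction = 0.6
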