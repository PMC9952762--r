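transcript_matrix = transcript.tsv
protein_matrix = protein.tsv
metabolite_matrix = metabolite.tsv
condition_map = condition_map.tsv
protein_lengths = protein_lengths.tsv
edge_list = edge_list.tsv
node_types = node_types.tsv
gmt = pathways.gmt
seed = 42
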