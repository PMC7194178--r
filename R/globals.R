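# data.table non-standard-evaluation column names
utils::globalVariables(c(
  ".", ".I", ".N", "assoc_p", "chrom", "combination", "count", "dataset",
  "datasets", "distance", "drug", "end", "enriched", "frag_a", "frag_b",
  "frag_id", "gene_id", "group", "id1", "id2", "info", "k", "phenotype",
  "pos", "pval_nominal", "q", "role", "rsid", "severity", "sig_differs",
  "significant", "start", "symbol", "tested", "tissue", "cis_trans",
  "observed", "r2", "rsid_a", "rsid_b"
))
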