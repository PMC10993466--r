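## Pinned md5 checksums of the packaged fixture tables. load_published_fixtures()
## refuses to serve a table whose file has drifted from the transcription.
fixture_checksums <- function() {
  list(
    table2_primate_sharing = "a6af8d9d33639b307b1cd291b6398602",
    table3_pathways = "2e81fe17592ef46d50fc4c4fd1af785a",
    table4_gene_counts = "a88235625f012eb429decf3839da73d1",
    table5_chek2 = "62a63022689cd2b7d9e68442ee452366",
    table6_founders = "5fa50323d7ca97fdb3dea9317b3fabe0",
    results_counts = "48f7bb716ba4f55cf10d3b0946c3fcdd")
}
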