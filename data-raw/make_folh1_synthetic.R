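# Builds the synthetic FOLH1 stand-in reference shipped in inst/extdata.
# A real curated FOLH1 sequence is deliberately not bundled; this synthetic
# 750-AA sequence carries the expected pocket residues at the canonical
# positions so the default pocket spec is internally consistent.
set.seed(20241204)
aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
len <- 750L
s <- sample(aa, len, replace = TRUE)
pocket <- c(
  `377` = "H", `387` = "D", `425` = "E", `453` = "D", `553` = "H",  # zinc binding
  `210` = "R", `257` = "N", `424` = "E", `518` = "G", `519` = "N",  # substrate binding
  `699` = "K", `700` = "Y",
  `463` = "R", `534` = "R", `536` = "R",                            # arginine patch
  `541` = "W", `548` = "G", `552` = "Y"                             # structural
)
s[as.integer(names(pocket))] <- pocket
seq <- paste(s, collapse = "")
lines <- c(
  ">FOLH1_SYNTHETIC synthetic FOLH1 stand-in reference (pocket residues planted at canonical positions)",
  substring(seq, seq(1, len, 60), pmin(seq(1, len, 60) + 59, len))
)
writeLines(lines, "inst/extdata/folh1_synthetic.fasta")
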