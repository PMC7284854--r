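# Generates inst/extdata/cas_panel_synthetic.fasta: one synthetic
# representative protein per cas gene per subtype, fixed seed so the file is
# reproducible. Run from the package root:
#   Rscript tools/make_panel.R

set.seed(20200512)

aa20 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")

# Realistic protein lengths (aa). Cas9 lengths match the gene sizes the
# pipeline is benchmarked against: II-A 4152 bp -> 1383 aa, II-C 3429 bp ->
# 1142 aa.
lengths <- list(
  cas1 = 300, cas2 = 110, cas3 = 900, cas4 = 180, cas5 = 230, cas6 = 240,
  cas6e = 200, cas7 = 320, cas8c = 560, cse1 = 500, cse2 = 180,
  cas8u2 = 400, cas1_4_fusion = 480, csn2 = 220,
  cas9_IIA = 1383, cas9_IIC = 1142
)

genes <- list(
  "I-C"  = c("cas3", "cas5", "cas8c", "cas7", "cas4", "cas1", "cas2"),
  "I-E"  = c("cas3", "cse1", "cse2", "cas7", "cas5", "cas6e", "cas1", "cas2"),
  "I-G"  = c("cas3", "cas8u2", "cas7", "cas5", "cas6", "cas1_4_fusion", "cas2"),
  "II-A" = c("cas9", "cas1", "cas2", "csn2"),
  "II-C" = c("cas9", "cas1", "cas2")
)

rand_protein <- function(len) {
  paste0("M", paste(sample(aa20, len - 1, replace = TRUE), collapse = ""))
}

lines <- character(0)
for (st in names(genes)) {
  type <- if (startsWith(st, "II")) "II" else "I"
  for (g in genes[[st]]) {
    key <- if (g == "cas9") paste0("cas9_", gsub("-", "", st)) else g
    len <- lengths[[key]]
    id <- paste0(g, "_", gsub("-", "", st))
    header <- paste(id, g, type, st, sep = "|")
    seq <- rand_protein(len)
    lines <- c(lines, paste0(">", header),
               substring(seq, seq(1, nchar(seq), 70),
                         pmin(seq(70, nchar(seq) + 69, 70), nchar(seq))))
  }
}

out <- file.path("inst", "extdata", "cas_panel_synthetic.fasta")
writeLines(lines, out)
cat("wrote", out, "with", sum(startsWith(lines, ">")), "records\n")
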