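# Reference lineages for common human gut genera. The synthetic community
# draws its taxa from this table so that LCA behaviour (congeneric species,
# shared families/phyla, a lone Verrucomicrobia member, ...) mirrors real
# gut metaproteomic data. All entries are Bacteria; the LCA engine itself is
# superkingdom-agnostic.
gut_genus_table <- function() {
  rows <- list(
    # phylum, class, order, family, genus
    c("Firmicutes", "Clostridia", "Eubacteriales", "Lachnospiraceae", "Blautia"),
    c("Firmicutes", "Clostridia", "Eubacteriales", "Lachnospiraceae", "Roseburia"),
    c("Firmicutes", "Clostridia", "Eubacteriales", "Lachnospiraceae", "Dorea"),
    c("Firmicutes", "Clostridia", "Eubacteriales", "Lachnospiraceae", "Coprococcus"),
    c("Firmicutes", "Clostridia", "Eubacteriales", "Lachnospiraceae", "Anaerostipes"),
    c("Firmicutes", "Clostridia", "Eubacteriales", "Lachnospiraceae", "Butyrivibrio"),
    c("Firmicutes", "Clostridia", "Eubacteriales", "Lachnospiraceae", "Lachnoclostridium"),
    c("Firmicutes", "Clostridia", "Eubacteriales", "Oscillospiraceae", "Faecalibacterium"),
    c("Firmicutes", "Clostridia", "Eubacteriales", "Oscillospiraceae", "Ruminococcus"),
    c("Firmicutes", "Clostridia", "Eubacteriales", "Oscillospiraceae", "Subdoligranulum"),
    c("Firmicutes", "Clostridia", "Eubacteriales", "Oscillospiraceae", "Oscillibacter"),
    c("Firmicutes", "Clostridia", "Eubacteriales", "Oscillospiraceae", "Anaerotruncus"),
    c("Firmicutes", "Clostridia", "Eubacteriales", "Clostridiaceae", "Clostridium"),
    c("Firmicutes", "Clostridia", "Eubacteriales", "Eubacteriaceae", "Eubacterium"),
    c("Firmicutes", "Clostridia", "Eubacteriales", "Peptostreptococcaceae", "Intestinibacter"),
    c("Firmicutes", "Negativicutes", "Veillonellales", "Veillonellaceae", "Veillonella"),
    c("Firmicutes", "Negativicutes", "Veillonellales", "Veillonellaceae", "Dialister"),
    c("Firmicutes", "Negativicutes", "Veillonellales", "Veillonellaceae", "Megasphaera"),
    c("Firmicutes", "Negativicutes", "Acidaminococcales", "Acidaminococcaceae", "Phascolarctobacterium"),
    c("Firmicutes", "Negativicutes", "Acidaminococcales", "Acidaminococcaceae", "Acidaminococcus"),
    c("Firmicutes", "Bacilli", "Lactobacillales", "Lactobacillaceae", "Lactobacillus"),
    c("Firmicutes", "Bacilli", "Lactobacillales", "Streptococcaceae", "Streptococcus"),
    c("Firmicutes", "Bacilli", "Lactobacillales", "Enterococcaceae", "Enterococcus"),
    c("Firmicutes", "Erysipelotrichia", "Erysipelotrichales", "Erysipelotrichaceae", "Holdemanella"),
    c("Firmicutes", "Erysipelotrichia", "Erysipelotrichales", "Erysipelotrichaceae", "Turicibacter"),
    c("Bacteroidetes", "Bacteroidia", "Bacteroidales", "Bacteroidaceae", "Bacteroides"),
    c("Bacteroidetes", "Bacteroidia", "Bacteroidales", "Prevotellaceae", "Prevotella"),
    c("Bacteroidetes", "Bacteroidia", "Bacteroidales", "Prevotellaceae", "Paraprevotella"),
    c("Bacteroidetes", "Bacteroidia", "Bacteroidales", "Rikenellaceae", "Alistipes"),
    c("Bacteroidetes", "Bacteroidia", "Bacteroidales", "Tannerellaceae", "Parabacteroides"),
    c("Bacteroidetes", "Bacteroidia", "Bacteroidales", "Odoribacteraceae", "Odoribacter"),
    c("Bacteroidetes", "Bacteroidia", "Bacteroidales", "Barnesiellaceae", "Barnesiella"),
    c("Actinobacteria", "Actinomycetia", "Bifidobacteriales", "Bifidobacteriaceae", "Bifidobacterium"),
    c("Actinobacteria", "Coriobacteriia", "Coriobacteriales", "Coriobacteriaceae", "Collinsella"),
    c("Actinobacteria", "Coriobacteriia", "Eggerthellales", "Eggerthellaceae", "Eggerthella"),
    c("Actinobacteria", "Coriobacteriia", "Eggerthellales", "Eggerthellaceae", "Gordonibacter"),
    c("Actinobacteria", "Coriobacteriia", "Eggerthellales", "Eggerthellaceae", "Slackia"),
    c("Actinobacteria", "Coriobacteriia", "Eggerthellales", "Eggerthellaceae", "Adlercreutzia"),
    c("Proteobacteria", "Gammaproteobacteria", "Enterobacterales", "Enterobacteriaceae", "Escherichia"),
    c("Proteobacteria", "Gammaproteobacteria", "Enterobacterales", "Enterobacteriaceae", "Klebsiella"),
    c("Proteobacteria", "Betaproteobacteria", "Burkholderiales", "Sutterellaceae", "Sutterella"),
    c("Proteobacteria", "Deltaproteobacteria", "Desulfovibrionales", "Desulfovibrionaceae", "Desulfovibrio"),
    c("Proteobacteria", "Deltaproteobacteria", "Desulfovibrionales", "Desulfovibrionaceae", "Bilophila"),
    c("Verrucomicrobia", "Verrucomicrobiae", "Verrucomicrobiales", "Akkermansiaceae", "Akkermansia"),
    c("Fusobacteria", "Fusobacteriia", "Fusobacteriales", "Fusobacteriaceae", "Fusobacterium")
  )
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(out) <- c("phylum", "class", "order", "family", "genus")
  out$superkingdom <- "Bacteria"
  out[, c("superkingdom", "phylum", "class", "order", "family", "genus")]
}

# One-letter COG functional categories used by the generator.
cog_categories <- function() {
  c("C", "E", "F", "G", "H", "I", "J", "K", "L", "M", "N", "O", "P", "T",
    "U", "V")
}
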