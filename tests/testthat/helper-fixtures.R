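# GFF3 / FASTA fixtures written to tempfiles at test time

writeGff3Fixture <- function(lines, path = tempfile(fileext = ".gff3")) {
    writeLines(c("##gff-version 3", lines), path)
    path
}

gffLine <- function(type, start, end, attrs, seqid = "chr1") {
    paste(seqid, "test", type, start, end, ".", "+", ".", attrs, sep = "\t")
}

# three genes exercising exon-sum length, span fallback and the
# equal-length tie rule
standardGffLines <- function() {
    c(gffLine("gene", 1, 5000, "ID=g1"),
      gffLine("mRNA", 1, 1000, "ID=g1.t1;Parent=g1"),
      gffLine("exon", 1, 200, "Parent=g1.t1"),
      gffLine("exon", 301, 400, "Parent=g1.t1"),       # exon sum 300
      gffLine("mRNA", 1, 450, "ID=g1.t2;Parent=g1"),   # span 450, no exons
      gffLine("gene", 6000, 9000, "ID=g2"),
      gffLine("mRNA", 6000, 6799, "ID=g2.t1;Parent=g2"),
      gffLine("gene", 10000, 15000, "ID=g3"),
      gffLine("mRNA", 10000, 10499, "ID=g3.tB;Parent=g3"),  # 500, tie
      gffLine("mRNA", 10100, 10599, "ID=g3.tA;Parent=g3"))  # 500, tie
}

writeFastaFixture <- function(seqs, path = tempfile(fileext = ".fa")) {
    con <- file(path, "w")
    for (nm in names(seqs)) {
        writeLines(paste0(">", nm), con)
        writeLines(paste(rep("A", seqs[[nm]]), collapse = ""), con)
    }
    close(con)
    path
}
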