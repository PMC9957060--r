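#' Filter assemblies by scaffold N50
#'
#' Drops species whose assembly scaffold N50 falls strictly below
#' \code{minN50} (default 400 kb): contiguity below that level is treated as
#' a low-quality genome whose annotation would bias family counts. The
#' boundary is retained: N50 equal to the threshold passes.
#'
#' @param records data.frame with columns \code{species_id} and
#'   \code{scaffold_n50} (bases).
#' @param minN50 threshold in bases (default 400000).
#' @return the subset of \code{records} with \code{scaffold_n50 >= minN50},
#'   original order preserved.
#' @examples
#' recs <- data.frame(species_id = c("spA", "spB"),
#'                    scaffold_n50 = c(350000, 900000))
#' filterAssemblies(recs)  # spB only
#' @export
filterAssemblies <- function(records, minN50 = 400000) {
    if (!is.data.frame(records) ||
        !all(c("species_id", "scaffold_n50") %in% names(records)))
        stop("records must be a data.frame with columns species_id and ",
             "scaffold_n50")
    if (minN50 <= 0) stop("minN50 must be > 0")
    n50 <- records$scaffold_n50
    bad <- which(!is.finite(n50) | n50 <= 0 | n50 != round(n50))
    if (length(bad) > 0L)
        stop("malformed scaffold_n50 in row ", bad[1], " (species '",
             records$species_id[bad[1]], "'): ", n50[bad[1]])
    dup <- duplicated(records$species_id)
    if (any(dup))
        stop("duplicate species_id: ", records$species_id[which(dup)[1]])
    records[n50 >= minN50, , drop = FALSE]
}

#' Pick the longest isoform per gene
#'
#' Alternative splicing leaves several mRNAs per gene in an annotation; for
#' family counting exactly one representative is kept — the longest. Length
#' is the transcript's sequence length: taken from \code{fastaFile} when the
#' transcript id is present there, otherwise the sum of the mRNA's exon
#' lengths from the GFF3, otherwise the mRNA feature's genomic span
#' (coordinates 1-based inclusive). Equal-length isoforms are resolved to
#' the lexicographically smallest transcript id, so the choice does not
#' depend on record order.
#'
#' @param gffFile path to a GFF3 annotation; mRNA features must carry a
#'   \code{Parent} gene attribute (orphan mRNAs are skipped with a warning),
#'   exons a \code{Parent} mRNA attribute.
#' @param fastaFile optional path to transcript sequences (FASTA); names
#'   must match mRNA IDs.
#' @return data.frame with columns \code{gene_id}, \code{transcript_id},
#'   \code{length}, one row per gene, ordered by gene id.
#' @export
selectLongestIsoform <- function(gffFile, fastaFile = NULL) {
    gr <- rtracklayer::import(gffFile, format = "gff3")
    typ <- as.character(gr$type)
    mrna <- gr[typ %in% c("mRNA", "transcript")]
    if (length(mrna) == 0L)
        stop("no mRNA features in ", gffFile)
    parent <- vapply(mrna$Parent, function(p)
        if (length(p) > 0L) p[[1]] else NA_character_, character(1))
    orphan <- is.na(parent)
    if (any(orphan)) {
        warning(sum(orphan), " mRNA feature(s) without a Parent gene ",
                "skipped: ", paste(utils::head(mrna$ID[orphan], 3),
                                   collapse = ", "))
        mrna <- mrna[!orphan]
        parent <- parent[!orphan]
    }
    txid <- mrna$ID
    parent <- sub("^gene:", "", parent)

    len <- BiocGenerics::width(mrna)           # genomic span fallback
    exons <- gr[typ == "exon"]
    if (length(exons) > 0L) {
        exParent <- vapply(exons$Parent, function(p)
            if (length(p) > 0L) p[[1]] else NA_character_, character(1))
        exSum <- tapply(BiocGenerics::width(exons), exParent, sum)
        hit <- txid %in% names(exSum)
        len[hit] <- as.integer(exSum[txid[hit]])
    }
    if (!is.null(fastaFile)) {
        seqs <- Biostrings::readDNAStringSet(fastaFile)
        names(seqs) <- sub("\\s.*$", "", names(seqs))
        hit <- txid %in% names(seqs)
        len[hit] <- BiocGenerics::width(seqs)[match(txid[hit], names(seqs))]
    }

    df <- data.frame(gene_id = parent, transcript_id = txid, length = len,
                     stringsAsFactors = FALSE)
    # longest first; ties to the lexicographically smallest transcript id
    df <- df[order(df$gene_id, -df$length, df$transcript_id), ]
    df <- df[!duplicated(df$gene_id), ]
    rownames(df) <- NULL
    df
}

#' Build the species-by-family count matrix
#'
#' Tallies a gene-to-family assignment table (one row per assigned gene)
#' into integer copy-number counts per species and family. Genes absent from
#' the table contribute nothing; a species listed in \code{speciesOrder} with
#' no assignments gets an all-zero row. Families observed nowhere are dropped
#' unless an explicit \code{familyOrder} pins the columns.
#'
#' @param assignments data.frame with columns \code{species_id},
#'   \code{gene_id}, \code{family_id}; duplicate (species, gene) rows are an
#'   error.
#' @param speciesOrder row order; defaults to order of first appearance.
#'   All species in \code{assignments} must be listed.
#' @param familyOrder optional column order; defaults to sorted unique
#'   family ids.
#' @param labels optional named character vector (names = species ids) or
#'   unnamed vector in \code{speciesOrder} order, attached as class labels.
#' @return a \linkS4class{GeneFamilyMatrix}.
#' @examples
#' asg <- data.frame(species_id = c("spA", "spA", "spA"),
#'                   gene_id = c("g1", "g2", "g3"),
#'                   family_id = c("TF101", "TF101", "TF102"))
#' familyCounts(buildFamilyMatrix(asg))
#' @export
buildFamilyMatrix <- function(assignments, speciesOrder = NULL,
                              familyOrder = NULL, labels = NULL) {
    need <- c("species_id", "gene_id", "family_id")
    if (!is.data.frame(assignments) || !all(need %in% names(assignments)))
        stop("assignments must be a data.frame with columns ",
             paste(need, collapse = ", "))
    key <- paste(assignments$species_id, assignments$gene_id, sep = "\r")
    dup <- duplicated(key)
    if (any(dup))
        stop("duplicate (species, gene) assignment: ",
             assignments$species_id[which(dup)[1]], " / ",
             assignments$gene_id[which(dup)[1]])
    if (is.null(speciesOrder))
        speciesOrder <- unique(assignments$species_id)
    missing <- setdiff(assignments$species_id, speciesOrder)
    if (length(missing) > 0L)
        stop("species in assignments but not in speciesOrder: ",
             paste(utils::head(missing, 3), collapse = ", "))
    if (is.null(familyOrder))
        familyOrder <- sort(unique(assignments$family_id))
    cts <- table(factor(assignments$species_id, levels = speciesOrder),
                 factor(assignments$family_id, levels = familyOrder))
    cts <- matrix(as.integer(cts), nrow = length(speciesOrder),
                  dimnames = list(speciesOrder, familyOrder))
    lab <- character(0)
    if (!is.null(labels)) {
        lab <- if (!is.null(names(labels))) {
            unmatched <- setdiff(speciesOrder, names(labels))
            if (length(unmatched) > 0L)
                stop("no label for species: ",
                     paste(utils::head(unmatched, 3), collapse = ", "))
            as.character(labels[speciesOrder])
        } else {
            if (length(labels) != length(speciesOrder))
                stop("unnamed labels must have one entry per species")
            as.character(labels)
        }
    }
    new("GeneFamilyMatrix", counts = cts, labels = lab)
}
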