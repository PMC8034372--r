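#' Construct a gene alignment object
#'
#' @param id Ortholog-group identifier.
#' @param seqs Named character vector of aligned DNA strings (equal
#'   lengths), or a character matrix (taxa x columns) of single
#'   characters.  Alphabet: `A C G T N - ?` (case-insensitive).
#' @param codon_aligned Are columns organized in codon triplets (length
#'   divisible by 3)?  Required by [strip_third_positions()].
#' @return A `gene_alignment`: list with `id`, `mat` (character matrix,
#'   rownames = taxa), `codon_aligned`.
#' @export
gene_alignment <- function(id, seqs, codon_aligned = FALSE) {
  if (is.matrix(seqs)) {
    mat <- toupper(seqs)
  } else {
    if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
      stop("sequences must be named by taxon")
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L)
      stop("aligned sequences must have equal lengths (OG '", id, "')")
    mat <- do.call(rbind, strsplit(toupper(unname(seqs)), "", fixed = TRUE))
    rownames(mat) <- names(seqs)
  }
  if (anyDuplicated(rownames(mat)))
    stop("duplicate taxon in alignment '", id, "'")
  bad <- setdiff(unique(as.vector(mat)), c("A", "C", "G", "T", "N", "-",
                                           "?"))
  if (length(bad))
    stop("illegal characters in alignment '", id, "': ",
         paste(bad, collapse = " "))
  if (codon_aligned && ncol(mat) %% 3L != 0L)
    stop("codon-aligned alignment '", id, "' has length not divisible by 3")
  structure(list(id = id, mat = mat, codon_aligned = codon_aligned),
            class = "gene_alignment")
}

#' Read a FASTA gene alignment
#'
#' @param path FASTA file of aligned DNA sequences.
#' @param id Ortholog-group id; defaults to the file name without
#'   extension.
#' @param codon_aligned See [gene_alignment()].
#' @return A `gene_alignment`.
#' @export
read_gene_alignment <- function(path, id = NULL, codon_aligned = FALSE) {
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  dna <- ape::read.FASTA(path)
  seqs <- vapply(as.character(dna), paste, character(1L), collapse = "")
  gene_alignment(id, seqs, codon_aligned = codon_aligned)
}

#' Write a gene alignment or supermatrix as FASTA
#'
#' @param x A `gene_alignment` or `supermatrix`.
#' @param path Output path.
#' @export
write_fasta <- function(x, path) {
  mat <- if (inherits(x, "supermatrix")) x$mat else x$mat
  con <- file(path, "w")
  on.exit(close(con))
  for (tx in rownames(mat)) {
    writeLines(paste0(">", tx), con)
    writeLines(paste(mat[tx, ], collapse = ""), con)
  }
  invisible(path)
}

#' Retain ortholog groups present in all required taxa
#'
#' The all-taxa occupancy rule: an alignment is kept only if its taxon set
#' contains every required taxon.  Input order is preserved.
#'
#' @param alignments List of `gene_alignment` objects.
#' @param required_taxa Character vector of taxa that must all be present.
#' @return The retained sublist.
#' @export
occupancy_filter <- function(alignments, required_taxa) {
  if (!length(required_taxa)) stop("'required_taxa' must be non-empty")
  keep <- vapply(alignments, function(a)
    all(required_taxa %in% rownames(a$mat)), logical(1L))
  alignments[keep]
}

#' Robinson-Foulds distance between two trees
#'
#' Both trees are pruned to their shared taxa and treated as unrooted
#' topologies (branch lengths ignored); the distance is the number of
#' non-trivial bipartitions present in exactly one tree (the symmetric
#' difference), always an even integer for binary trees.
#'
#' @param t1,t2 `phylo` objects.
#' @return Integer RF distance.
#' @export
rf_distance <- function(t1, t2) {
  shared <- intersect(t1$tip.label, t2$tip.label)
  if (length(shared) < 4L)
    stop("fewer than 4 shared taxa; RF distance undefined")
  p1 <- ape::unroot(ape::keep.tip(t1, shared))
  p2 <- ape::unroot(ape::keep.tip(t2, shared))
  as.integer(phangorn::RF.dist(p1, p2, normalize = FALSE,
                               check.labels = TRUE))
}

#' Filter gene trees by Robinson-Foulds distance to a reference
#'
#' A gene tree (and its alignment) is retained only when its RF distance
#' to the reference tree, computed on the shared taxon set, is below the
#' threshold; a distance greater than or equal to the threshold discards
#' it.  Trees for which the distance is undefined (fewer than 4 shared
#' taxa) are discarded with a recorded reason.
#'
#' @param gene_trees Named list of `phylo` gene trees (names = OG ids).
#' @param reference Reference `phylo` tree.
#' @param threshold Discard threshold (default 6: an RF score of 6 or more
#'   discards).
#' @return List with `retained` (ids), `discarded` (ids) and `report`
#'   (data frame: `id`, `shared_taxa`, `rf`, `decision`, `reason`).
#' @export
filter_by_rf <- function(gene_trees, reference, threshold = 6L) {
  if (threshold < 0L) stop("'threshold' must be non-negative")
  ids <- names(gene_trees)
  if (is.null(ids)) ids <- paste0("og", seq_along(gene_trees))
  rows <- lapply(seq_along(gene_trees), function(i) {
    gt <- gene_trees[[i]]
    shared <- length(intersect(gt$tip.label, reference$tip.label))
    rf <- tryCatch(rf_distance(gt, reference), error = function(e) NA_integer_)
    if (is.na(rf)) {
      data.frame(id = ids[i], shared_taxa = shared, rf = NA_integer_,
                 decision = "discarded", reason = "fewer than 4 shared taxa",
                 stringsAsFactors = FALSE)
    } else {
      keep <- rf < threshold
      data.frame(id = ids[i], shared_taxa = shared, rf = rf,
                 decision = if (keep) "retained" else "discarded",
                 reason = if (keep) "" else "RF at or above threshold",
                 stringsAsFactors = FALSE)
    }
  })
  report <- do.call(rbind, rows)
  list(retained = report$id[report$decision == "retained"],
       discarded = report$id[report$decision == "discarded"],
       report = report)
}

#' Remove third codon positions from an alignment
#'
#' Drops every third alignment column (3, 6, 9, ...) of a codon-aligned
#' matrix, the usual mitigation when third-position saturation distorts
#' phylogenetic signal.  Counting is by alignment column, not by ungapped
#' sequence position, since codon-aware alignment keeps columns in
#' triplets.
#'
#' @param aln A codon-aligned `gene_alignment`.
#' @return A `gene_alignment` of 2/3 the original length, no longer
#'   flagged codon-aligned.
#' @export
strip_third_positions <- function(aln) {
  if (!inherits(aln, "gene_alignment")) stop("not a gene_alignment")
  if (!aln$codon_aligned)
    stop("alignment '", aln$id, "' is not codon-aligned")
  keep <- seq_len(ncol(aln$mat)) %% 3L != 0L
  gene_alignment(aln$id, aln$mat[, keep, drop = FALSE],
                 codon_aligned = FALSE)
}

#' Concatenate gene alignments into a supermatrix
#'
#' Concatenates alignments over the union of their taxa, filling missing
#' taxon-gene blocks with `?`, and records the partition table (1-based
#' inclusive column intervals per gene) and the completeness percentage:
#' `100 x` the fraction of cells that are unambiguous nucleotides
#' (`A/C/G/T`; `N`, `-` and `?` count as missing).
#'
#' @param alignments Non-empty list of `gene_alignment` objects with
#'   unique ids.
#' @return A `supermatrix`: list with `mat` (character matrix), `partitions`
#'   (data frame `gene`, `start`, `end`), `completeness` (percent), `n_taxa`,
#'   `n_char`.
#' @export
concatenate_alignments <- function(alignments) {
  if (!length(alignments)) stop("no alignments to concatenate")
  ids <- vapply(alignments, `[[`, character(1L), "id")
  if (anyDuplicated(ids))
    stop("duplicate gene ids: ", paste(unique(ids[duplicated(ids)]),
                                       collapse = ", "))
  taxa <- sort(unique(unlist(lapply(alignments, function(a)
    rownames(a$mat)))))
  lens <- vapply(alignments, function(a) ncol(a$mat), integer(1L))
  total <- sum(lens)
  mat <- matrix("?", length(taxa), total, dimnames = list(taxa, NULL))
  start <- cumsum(c(1L, lens[-length(lens)]))
  end <- cumsum(lens)
  for (i in seq_along(alignments)) {
    a <- alignments[[i]]
    mat[rownames(a$mat), start[i]:end[i]] <- a$mat
  }
  completeness <- 100 * sum(mat %in% c("A", "C", "G", "T")) /
    (length(taxa) * total)
  structure(list(mat = mat,
                 partitions = data.frame(gene = ids, start = start,
                                         end = end,
                                         stringsAsFactors = FALSE),
                 completeness = completeness,
                 n_taxa = length(taxa), n_char = total),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' One-line supermatrix descriptor
#'
#' @param x A `supermatrix`.
#' @param ... Ignored.
#' @return A string like
#'   `"96% complete DNA alignment of 48 taxa and 89,302 characters"`.
#' @export
format.supermatrix <- function(x, ...) {
  sprintf("%d%% complete DNA alignment of %d taxa and %s characters",
          round(x$completeness), x$n_taxa,
          formatC(x$n_char, big.mark = ",", format = "d"))
}

#' Write a RAxML-style partition file
#'
#' One line per gene: `DNA, <gene> = <start>-<end>`.
#'
#' @param sm A `supermatrix`.
#' @param path Output path.
#' @export
write_partitions <- function(sm, path) {
  writeLines(sprintf("DNA, %s = %d-%d", sm$partitions$gene,
                     sm$partitions$start, sm$partitions$end), path)
  invisible(path)
}
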