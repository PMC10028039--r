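# Degenerate motif expansion and duplex binding-site scanning.
#
# Scanning is done with overlap-tolerant PCRE lookahead on the forward
# strand: the motif in both its given orientation and its reverse
# complement. IUPAC symbols in the motif become explicit A/C/G/T character
# classes, so an ambiguity base N in the *sequence* never matches (a
# deterministic-count convention for duplex site tallies).

.IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

.IUPAC_COMP <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                 S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
                 D = "H", H = "D", N = "N")

.motif_string <- function(m) {
  if (inherits(m, "degenerate_motif")) m$iupac
  else if (is.character(m) && length(m) == 1L) toupper(m)
  else stop("motif must be a degenerate_motif or a single string")
}

#' Reverse complement of an IUPAC string
#'
#' @param x single DNA string (degenerate symbols allowed).
#' @return The reverse complement, degeneracy preserved.
#' @export
reverse_complement <- function(x) {
  chars <- rev(strsplit(toupper(x), "")[[1]])
  bad <- setdiff(chars, names(.IUPAC_COMP))
  if (length(bad)) stop("cannot complement symbol(s): ",
                        paste(bad, collapse = ""))
  paste(.IUPAC_COMP[chars], collapse = "")
}

#' Expand a degenerate motif into its concrete sequences
#'
#' @param m a [degenerate_motif()] or IUPAC string.
#' @return Sorted character vector; length is the product of per-position
#'   degeneracies (W contributes 2, N contributes 4, fixed bases 1).
#' @examples
#' expand_motif("WN")  # 8 sequences
#' @export
expand_motif <- function(m) {
  iupac <- .motif_string(m)
  sets <- .IUPAC[strsplit(iupac, "")[[1]]]
  if (anyNA(names(sets))) stop("invalid IUPAC symbol in motif")
  grid <- do.call(expand.grid,
                  c(rev(sets), KEEP.OUT.ATTRS = FALSE,
                    stringsAsFactors = FALSE))
  sort(do.call(paste0, rev(grid)))
}

.motif_regex <- function(iupac) {
  cls <- vapply(.IUPAC[strsplit(iupac, "")[[1]]], function(s) {
    if (length(s) == 1L) s else paste0("[", paste(s, collapse = ""), "]")
  }, character(1))
  paste0("(?=", paste(cls, collapse = ""), ")")
}

.find_starts <- function(seq, iupac) {
  # 1-based starts of all (overlapping) matches on the forward strand
  m <- gregexpr(.motif_regex(iupac), seq, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

#' Scan a duplex sequence for motif binding sites
#'
#' Reports every position where the motif matches the forward strand
#' (orientation `+`) and every position where its reverse complement does
#' (orientation `-`; i.e. the motif reads 5'->3' on the minus strand).
#' A position matching in both orientations (a palindromic concrete match)
#' is reported once with orientation `+`, so each physical duplex site is
#' counted exactly once.
#'
#' @param seq A/C/G/T(/N) string; lowercase is uppercased unless
#'   `respect_softmask = TRUE`, in which case soft-masked bases never match.
#' @param m a [degenerate_motif()] or IUPAC string.
#' @param seq_id record identifier carried on the result.
#' @param respect_softmask keep lowercase (masked) bases unmatchable.
#' @return `data.frame` with columns `seq_id`, `start`, `end` (0-based
#'   half-open), `orientation`, `matched`, sorted by `start` then
#'   orientation.
#' @export
scan_duplex <- function(seq, m, seq_id = "seq", respect_softmask = FALSE) {
  iupac <- .motif_string(m)
  if (!nzchar(iupac)) stop("empty motif")
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!respect_softmask) seq <- toupper(seq)
  w <- nchar(iupac)
  fwd <- .find_starts(seq, iupac)
  rc <- reverse_complement(iupac)
  rev <- .find_starts(seq, rc)
  rev <- setdiff(rev, fwd)  # palindromic duplex sites reported once, as +
  starts <- c(fwd, rev)
  if (!length(starts))
    return(data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), orientation = character(0),
                      matched = character(0), stringsAsFactors = FALSE))
  ori <- c(rep("+", length(fwd)), rep("-", length(rev)))
  o <- order(starts, match(ori, c("+", "-")))
  starts <- starts[o]; ori <- ori[o]
  data.frame(seq_id = rep(seq_id, length(starts)),
             start = starts - 1L,
             end = starts - 1L + w,
             orientation = ori,
             matched = substring(seq, starts, starts + w - 1L),
             stringsAsFactors = FALSE)
}

#' Count motif sites across a FASTA file
#'
#' Streams over records (one record in memory at a time) and applies
#' [scan_duplex()] to each; sites never span record boundaries.
#'
#' @param fasta path to a (multi-record) FASTA file.
#' @param m a [degenerate_motif()] or IUPAC string.
#' @param respect_softmask see [scan_duplex()].
#' @return List with `per_record` (named integer vector) and `total`.
#' @export
count_sites_fasta <- function(fasta, m, respect_softmask = FALSE) {
  if (!file.exists(fasta)) stop("FASTA not found: ", fasta)
  idx <- Biostrings::fasta.index(fasta)
  counts <- integer(nrow(idx))
  ids <- character(nrow(idx))
  for (i in seq_len(nrow(idx))) {
    rec <- Biostrings::readBStringSet(idx[i, ])
    ids[i] <- sub("\\s.*$", "", names(rec)[1])
    counts[i] <- nrow(scan_duplex(as.character(rec[[1]]), m,
                                  seq_id = ids[i],
                                  respect_softmask = respect_softmask))
  }
  names(counts) <- ids
  list(per_record = counts, total = sum(counts))
}

#' Scan every record of a FASTA file for motif sites
#'
#' @inheritParams count_sites_fasta
#' @param name site name written to the BED `name` column (e.g. compound).
#' @return `data.frame` of sites as in [scan_duplex()], plus a `name` column.
#' @export
scan_fasta <- function(fasta, m, name = "site", respect_softmask = FALSE) {
  if (!file.exists(fasta)) stop("FASTA not found: ", fasta)
  seqs <- Biostrings::readBStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  out <- do.call(rbind, lapply(names(seqs), function(id)
    scan_duplex(as.character(seqs[[id]]), m, seq_id = id,
                respect_softmask = respect_softmask)))
  if (is.null(out))
    out <- data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), orientation = character(0),
                      matched = character(0))
  out$name <- rep(name, nrow(out))
  out
}

#' Count binding sites per gene
#'
#' A site counts for a gene iff its interval overlaps the gene interval by
#' at least one base on the same `seq_id`, regardless of gene strand (a
#' minor-groove binder sees the duplex). Genes with no site are reported
#' with count 0.
#'
#' @param sites site `data.frame` from [scan_duplex()] / [scan_fasta()]
#'   (0-based half-open coordinates).
#' @param genes gene interval `data.frame` with columns `gene_id`, `seq_id`,
#'   `start`, `end` (0-based half-open), `strand`.
#' @return Named integer vector of site counts, one entry per gene.
#' @export
annotate_sites <- function(sites, genes) {
  stopifnot(all(c("gene_id", "seq_id", "start", "end") %in% names(genes)))
  if (anyDuplicated(genes$gene_id))
    stop("gene_id must be unique in the annotation")
  counts <- integer(nrow(genes))
  names(counts) <- genes$gene_id
  if (nrow(sites) == 0L || nrow(genes) == 0L) return(counts)
  gr_genes <- GenomicRanges::GRanges(
    genes$seq_id, IRanges::IRanges(genes$start + 1L, genes$end))
  gr_sites <- GenomicRanges::GRanges(
    sites$seq_id, IRanges::IRanges(sites$start + 1L, sites$end))
  # sites on seq_ids absent from the annotation legitimately match nothing
  n <- suppressWarnings(
    GenomicRanges::countOverlaps(gr_genes, gr_sites, minoverlap = 1L))
  counts[] <- n
  counts
}
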