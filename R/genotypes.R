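#' Read per-locus alignments from FASTA
#'
#' One FASTA per locus, record identifiers equal to isolate identifiers.
#' Within a locus all sequences must be aligned to the same length.
#' Isolates missing from any locus are rejected (the analysis uses only
#' fully genotyped isolates); use `intersect_isolates = TRUE` to drop them
#' instead.
#'
#' @param files Named character vector of FASTA paths; names are locus
#'   names and define the concatenation order. Default locus order is the
#'   five-locus panel `Mxan_0128, Mxan_0533, Mxan_1277, Mxan_4405, Mxan_5783`.
#' @param intersect_isolates Drop isolates absent from some locus instead
#'   of erroring.
#' @return A `locus_alignment_set`: named list (locus -> named character
#'   vector of aligned sequences, uppercase).
#' @export
read_locus_alignments <- function(files, intersect_isolates = FALSE) {
  if (is.null(names(files)) || any(!nzchar(names(files)))) {
    stop("`files` must be a named vector; names are locus names")
  }
  aln <- lapply(files, function(f) {
    x <- Biostrings::readBStringSet(f)
    s <- toupper(as.character(x))
    names(s) <- sub("\\s.*$", "", names(x))
    s
  })
  locus_alignment_set(aln, intersect_isolates = intersect_isolates)
}

#' Construct and validate a per-locus alignment set
#'
#' @param alignments Named list: locus -> named character vector of aligned
#'   sequences (alphabet `A/C/G/T/N/-`).
#' @inheritParams read_locus_alignments
#' @return A `locus_alignment_set` object.
#' @export
locus_alignment_set <- function(alignments, intersect_isolates = FALSE) {
  stopifnot(is.list(alignments), length(alignments) >= 1L,
            !is.null(names(alignments)))
  alignments <- lapply(alignments, function(s) {
    stopifnot(is.character(s), !is.null(names(s)))
    toupper(s)
  })
  for (locus in names(alignments)) {
    w <- nchar(alignments[[locus]])
    if (length(unique(w)) != 1L) {
      stop("ragged alignment at locus ", locus,
           ": sequence lengths ", paste(unique(w), collapse = ", "))
    }
    chars <- unique(strsplit(paste(alignments[[locus]], collapse = ""), "")[[1]])
    bad <- setdiff(chars, c("A", "C", "G", "T", "N", "-"))
    if (length(bad)) {
      stop("locus ", locus, " contains characters outside A/C/G/T/N/-: ",
           paste(bad, collapse = " "))
    }
  }
  ids <- lapply(alignments, names)
  common <- Reduce(intersect, ids)
  all_ids <- unique(unlist(ids))
  if (length(common) < length(all_ids)) {
    missing <- lapply(names(alignments), function(l) setdiff(all_ids, ids[[l]]))
    names(missing) <- names(alignments)
    missing <- missing[lengths(missing) > 0]
    if (!intersect_isolates) {
      msg <- vapply(names(missing), function(l)
        paste0(l, ": ", paste(missing[[l]], collapse = ", ")), character(1))
      stop("isolate(s) missing from some loci (exclude them first or use ",
           "intersect_isolates = TRUE):\n  ", paste(msg, collapse = "\n  "))
    }
    alignments <- lapply(alignments, function(s) s[common])
  } else {
    alignments <- lapply(alignments, function(s) s[common])
  }
  if (length(common) == 0L) stop("no isolate is present at every locus")
  structure(alignments, class = "locus_alignment_set")
}

#' Concatenate per-locus alignments into multilocus concatemers
#'
#' Loci are joined in the order of the alignment set, preserving alignment
#' gaps, so every concatemer has the same length (the sum of the locus
#' alignment lengths; 1445 bp including gaps for the five-locus panel).
#'
#' @param aligned A `locus_alignment_set`.
#' @return Named character vector of concatemers (class `concatemer_set`),
#'   with attributes `loci` and `locus_lengths`.
#' @export
concatenate_loci <- function(aligned) {
  if (!inherits(aligned, "locus_alignment_set")) {
    aligned <- locus_alignment_set(aligned)
  }
  ids <- names(aligned[[1L]])
  parts <- lapply(aligned, function(s) s[ids])
  concat <- do.call(paste0, parts)
  names(concat) <- ids
  structure(concat,
            class = "concatemer_set",
            loci = names(aligned),
            locus_lengths = vapply(aligned, function(s) nchar(s[[1L]]),
                                   integer(1)))
}

#' Assign sequence types by exact concatemer identity
#'
#' Two isolates share a sequence type (ST) if and only if their concatemers
#' are identical strings; gaps and N count as ordinary characters. ST
#' labels are positive integers in order of first occurrence in the input.
#'
#' @param concatemers Named character vector of equal-length sequences.
#' @return List with `st` (named integer vector isolate -> ST label) and
#'   `n_st` (number of distinct STs).
#' @export
assign_sequence_types <- function(concatemers) {
  if (length(concatemers) == 0L) stop("no concatemers supplied")
  if (is.null(names(concatemers))) stop("concatemers must be named by isolate")
  if (length(unique(nchar(concatemers))) != 1L) {
    stop("concatemers must all have the same length")
  }
  u <- unique(unname(concatemers))
  st <- match(concatemers, u)
  names(st) <- names(concatemers)
  list(st = st, n_st = length(u))
}

# Sites where either sequence has a gap or N are excluded from that pair's
# comparison (pairwise deletion); "complete" drops such columns globally.
as_dnabin <- function(seqs) {
  ape::as.DNAbin(lapply(seqs, function(s) strsplit(s, "")[[1]]))
}

drop_ambiguous_columns <- function(seqs) {
  m <- do.call(rbind, strsplit(unname(seqs), ""))
  keep <- colSums(m == "-" | m == "N") == 0L
  if (!any(keep)) stop("no site free of gaps/N under complete deletion")
  out <- apply(m[, keep, drop = FALSE], 1L, paste, collapse = "")
  names(out) <- names(seqs)
  out
}

raw_distance_matrix <- function(seqs, site_handling) {
  if (site_handling == "complete") seqs <- drop_ambiguous_columns(seqs)
  d <- ape::dist.dna(as_dnabin(seqs), model = "raw", pairwise.deletion = TRUE)
  as.matrix(d)
}

#' Nucleotide diversity of a set of aligned sequences
#'
#' The average proportion of differing nucleotide sites over all unordered
#' sequence pairs. Under the default pairwise deletion, sites with a gap or
#' N in either member of a pair are excluded from that pair's comparison.
#'
#' @param seqs Named character vector of >= 2 equal-length aligned sequences.
#' @param site_handling `"pairwise"` (default) or `"complete"` deletion.
#' @return List with `pi`, `n` (number of sequences) and `sites_used`
#'   (alignment sites entering at least one comparison).
#' @export
#' @examples
#' nucleotide_diversity(c(a = "AAAA", b = "AAAT"))$pi  # 0.25
nucleotide_diversity <- function(seqs,
                                 site_handling = c("pairwise", "complete")) {
  site_handling <- match.arg(site_handling)
  if (length(seqs) < 2L) stop("nucleotide diversity needs at least 2 sequences")
  if (length(unique(nchar(seqs))) != 1L) stop("sequences must be equal length")
  dm <- raw_distance_matrix(seqs, site_handling)
  up <- dm[upper.tri(dm)]
  if (anyNA(up) || any(is.nan(up))) {
    idx <- which(is.na(dm) | is.nan(dm), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    pairs <- apply(idx, 1L, function(i)
      paste(rownames(dm)[i[1]], rownames(dm)[i[2]], sep = " vs "))
    stop("no comparable sites for pair(s): ", paste(pairs, collapse = "; "))
  }
  m <- do.call(rbind, strsplit(unname(seqs), ""))
  sites_used <- sum(colSums(m != "-" & m != "N") >= 2L)
  list(pi = mean(up), n = length(seqs), sites_used = sites_used,
       site_handling = site_handling)
}

#' Pairwise genetic distance between two aligned sequences
#'
#' `"p"` is the proportion of mismatching comparable sites; `"JC69"`
#' applies the Jukes-Cantor correction `-(3/4) log(1 - 4p/3)`; `"K2P"` is
#' the Kimura two-parameter distance from transition and transversion
#' proportions. Distances are computed with `ape::dist.dna`.
#'
#' @param a,b Aligned sequences (equal-length character scalars).
#' @param model `"p"`, `"JC69"` or `"K2P"`.
#' @param site_handling `"pairwise"` or `"complete"` deletion of gap/N sites.
#' @param saturated Policy when the correction is undefined (p >= 0.75
#'   under JC69, or the analogous K2P condition): `"error"` or `"inf"`
#'   (returns `Inf` as a saturation sentinel).
#' @return Non-negative distance (substitutions per site).
#' @export
#' @examples
#' pairwise_distance("ACGT", "ACGA", model = "p")  # 0.25
pairwise_distance <- function(a, b, model = c("p", "JC69", "K2P"),
                              site_handling = c("pairwise", "complete"),
                              saturated = c("error", "inf")) {
  model <- match.arg(model)
  saturated <- match.arg(saturated)
  site_handling <- match.arg(site_handling)
  stopifnot(is.character(a), is.character(b),
            length(a) == 1L, length(b) == 1L)
  if (nchar(a) != nchar(b)) stop("sequences must be equal length")
  d <- genetic_distances(c(a = a, b = b), model = model,
                         site_handling = site_handling, saturated = saturated)
  d["a", "b"]
}

#' Pairwise genetic distance matrix for a set of sequences
#'
#' @param seqs Named character vector of equal-length aligned sequences.
#' @inheritParams pairwise_distance
#' @return Symmetric matrix with zero diagonal; attributes `model` and
#'   `site_handling` record the options used.
#' @export
genetic_distances <- function(seqs, model = c("p", "JC69", "K2P"),
                              site_handling = c("pairwise", "complete"),
                              saturated = c("error", "inf")) {
  model <- match.arg(model)
  saturated <- match.arg(saturated)
  site_handling <- match.arg(site_handling)
  if (length(unique(nchar(seqs))) != 1L) stop("sequences must be equal length")
  if (site_handling == "complete") seqs <- drop_ambiguous_columns(seqs)
  ape_model <- c(p = "raw", JC69 = "JC69", K2P = "K80")[model]
  dm <- as.matrix(ape::dist.dna(as_dnabin(seqs), model = ape_model,
                                pairwise.deletion = TRUE))
  bad <- is.na(dm) | is.nan(dm) | dm < 0
  diag(bad) <- FALSE
  if (any(bad)) {
    if (model == "p") {
      idx <- which(bad & upper.tri(bad), arr.ind = TRUE)
      pairs <- apply(idx, 1L, function(i)
        paste(rownames(dm)[i[1]], rownames(dm)[i[2]], sep = " vs "))
      stop("no comparable sites for pair(s): ", paste(pairs, collapse = "; "))
    }
    if (saturated == "error") {
      stop("saturated distance(s) under ", model,
           " (divergence too high for the correction); ",
           "use saturated = \"inf\" to keep them as Inf")
    }
    dm[bad] <- Inf
  }
  structure(dm, model = model, site_handling = site_handling)
}

#' Sequence-type and diversity summary across the nested design
#'
#' One row per nested group at every level (overall, site, transect, core,
#' fruiting body): sample size, number of distinct sequence types, and
#' nucleotide diversity. Diversity is `NA` for groups with fewer than two
#' isolates.
#'
#' @param sheet Sample sheet (see [parse_isolate_id()]).
#' @param concatemers Named character vector of concatemers covering every
#'   isolate in `sheet`.
#' @param site_handling Passed to [nucleotide_diversity()].
#' @return Data frame with columns `level`, `group`, `n`, `st_count`, `pi`.
#' @export
diversity_table <- function(sheet, concatemers,
                            site_handling = c("pairwise", "complete")) {
  site_handling <- match.arg(site_handling)
  missing <- setdiff(sheet$isolate_id, names(concatemers))
  if (length(missing)) {
    stop("no concatemer for isolate(s): ", paste(missing, collapse = ", "))
  }
  st <- assign_sequence_types(concatemers[sheet$isolate_id])$st
  keys <- list(
    overall = rep("all", nrow(sheet)),
    site = sheet$site,
    transect = paste0(sheet$site, sheet$transect),
    core = paste0(sheet$site, sheet$transect, ".", sheet$core),
    fruiting_body = paste0(sheet$site, sheet$transect, ".", sheet$core, ".",
                           sheet$fruiting_body)
  )
  rows <- lapply(names(keys), function(level) {
    split_idx <- split(seq_len(nrow(sheet)), keys[[level]])
    do.call(rbind, lapply(names(split_idx), function(g) {
      i <- split_idx[[g]]
      ids <- sheet$isolate_id[i]
      pi <- if (length(i) >= 2L) {
        nucleotide_diversity(concatemers[ids], site_handling)$pi
      } else NA_real_
      data.frame(level = level, group = g, n = length(i),
                 st_count = length(unique(st[ids])), pi = pi)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
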