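# Whole-genome summary statistics for a genome plus its annotation.

#' Summarise a genome and its annotation
#'
#' Computes the summary statistics conventionally reported for an annotated
#' NPV genome: base composition, ORF counts and orientations, coding totals
#' (both the plain span sum and the overlap-collapsed union), pairwise ORF
#' overlaps, promoter tallies, and hr sizes.  ORF "nominal" lengths follow
#' the 3 x aa convention (stop codon excluded); genomic spans include the
#' stop.
#'
#' @param ann an \code{\link{annotation_set}}.
#' @param genome optional \code{\link{circular_genome}}; sequence-dependent
#'   fields (GC/AT percent) are NA without it.  N bases are excluded from
#'   composition percentages.
#' @return a list of class \code{genome_summary}; see Details for fields.
#' @details Fields: \code{genome_length}, \code{gc_percent},
#'   \code{at_percent}, \code{n_orfs}, \code{total_aa},
#'   \code{total_coding_nt} (sum of inclusive spans),
#'   \code{union_coding_nt} (overlap-collapsed), \code{hr_total_nt},
#'   \code{hr_lengths}, \code{hr_fraction_percent}, \code{intergenic_nt}
#'   (= length - union coding - hr), \code{n_forward}, \code{n_reverse},
#'   \code{largest_orf} / \code{smallest_orf} (index, name, nominal bp),
#'   \code{n_overlapping_orfs}, \code{n_overlapping_pairs},
#'   \code{total_overlap_nt}, \code{min_overlap_nt}, \code{max_overlap_nt},
#'   \code{promoter_tally}, \code{mean_orf_nominal_bp},
#'   \code{mean_orf_span_bp}.
#' @export
summarize_genome <- function(ann, genome = NULL) {
    stopifnot(inherits(ann, "annotation_set"))
    L <- ann$genome_length
    orfs <- ann$orfs
    n <- nrow(orfs)
    gc <- at <- NA_real_
    if (!is.null(genome)) {
        v <- .as_bases(genome$sequence)
        v <- v[v != "N"]
        gc <- 100 * mean(v %in% c("G", "C"))
        at <- 100 * mean(v %in% c("A", "T"))
    }
    span <- if (n) orf_span_nt(orfs$start, orfs$end, orfs$wrap, L) else integer()
    # overlap-collapsed coding footprint
    covered <- logical(L)
    if (n) {
        for (i in seq_len(n)) {
            for (p in seq_len(nrow(.span_pieces(orfs$start[i], orfs$end[i],
                                                orfs$wrap[i], L)))) {
                piece <- .span_pieces(orfs$start[i], orfs$end[i], orfs$wrap[i], L)[p, ]
                covered[piece[1L]:piece[2L]] <- TRUE
            }
        }
    }
    union_coding <- sum(covered)
    hr_len <- if (nrow(ann$hrs)) ann$hrs$end - ann$hrs$start + 1L else integer()
    # pairwise overlap statistics over all ORF pairs with intersecting spans
    ov_list <- numeric()
    ov_orfs <- integer()
    if (n >= 2L) {
        for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
            ov <- .span_overlap(orfs$start[i], orfs$end[i], orfs$wrap[i],
                                orfs$start[j], orfs$end[j], orfs$wrap[j], L)
            if (ov > 0L) {
                ov_list <- c(ov_list, ov)
                ov_orfs <- c(ov_orfs, orfs$index[i], orfs$index[j])
            }
        }
    }
    pick <- function(i) list(index = orfs$index[i], name = orfs$name[i],
                             nominal_bp = 3L * orfs$length_aa[i])
    structure(list(
        genome_length = L, gc_percent = gc, at_percent = at,
        n_orfs = n, total_aa = sum(orfs$length_aa),
        total_coding_nt = sum(span), union_coding_nt = union_coding,
        hr_total_nt = sum(hr_len), hr_lengths = hr_len,
        hr_fraction_percent = 100 * sum(hr_len) / L,
        intergenic_nt = L - union_coding - sum(hr_len),
        n_forward = sum(orfs$strand == "+"), n_reverse = sum(orfs$strand == "-"),
        largest_orf = if (n) pick(which.max(orfs$length_aa)) else NULL,
        smallest_orf = if (n) pick(which.min(orfs$length_aa)) else NULL,
        n_overlapping_orfs = length(unique(ov_orfs)),
        n_overlapping_pairs = length(ov_list),
        total_overlap_nt = sum(ov_list),
        min_overlap_nt = if (length(ov_list)) min(ov_list) else NA_integer_,
        max_overlap_nt = if (length(ov_list)) max(ov_list) else NA_integer_,
        promoter_tally = promoter_tally(ann),
        mean_orf_nominal_bp = if (n) mean(3L * orfs$length_aa) else NA_real_,
        mean_orf_span_bp = if (n) mean(span) else NA_real_),
        class = "genome_summary")
}

#' @export
print.genome_summary <- function(x, ...) {
    cat(sprintf("<genome_summary> %s bp, %d ORFs (%d+/%d-), %d aa total\n",
                format(x$genome_length, big.mark = ","), x$n_orfs,
                x$n_forward, x$n_reverse, x$total_aa))
    cat(sprintf("  coding: %d nt span-sum, %d nt union; hrs: %d nt (%.2f%%); intergenic: %d nt\n",
                x$total_coding_nt, x$union_coding_nt, x$hr_total_nt,
                x$hr_fraction_percent, x$intergenic_nt))
    invisible(x)
}
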