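# Six-frame ORF prediction on circular genomes.
#
# The calling criterion is the classic NPV-annotation rule: an ORF starts at
# the first ATG of a stop-to-stop interval, encodes at least `min_aa` amino
# acids (initiator Met counted, stop excluded; so the 50-aa threshold is met
# by a 153-nt genomic span), and overlap between retained ORFs is capped by a
# greedy longest-first selection.

.STOP_CODONS <- c("TAA", "TAG", "TGA")

# scan one linear sequence (already oriented 5'->3') for first-ATG candidates.
# Returns positions in the coordinates of `seq`.  When `require_left_stop` is
# TRUE (circular scan over a doubled sequence), the leading interval of each
# frame - which is a truncated view of an interval whose true left stop lies
# further along the circle - is skipped; `left_stop` carries the nucleotide
# position of each interval's bounding stop so the caller can keep exactly one
# copy of every cyclic interval.
.scan_frames <- function(seq, min_aa, require_left_stop = FALSE, max_aa = Inf) {
    n <- nchar(seq)
    out <- vector("list", 3L)
    for (f in 0:2) {
        p <- seq.int(f + 1L, n - 2L, by = 3L)
        if (length(p) < 2L) next
        codons <- substring(seq, p, p + 2L)
        is_stop <- codons %in% .STOP_CODONS
        is_atg <- codons == "ATG"
        has_n <- grepl("N", codons, fixed = TRUE)
        stops <- which(is_stop)
        if (!length(stops)) next
        bounds <- c(0L, stops)              # interval i: (bounds[i]+1) .. stops[i]
        res <- list()
        csum_n <- cumsum(has_n)
        for (i in seq_along(stops)) {
            if (require_left_stop && bounds[i] == 0L) next
            lo <- bounds[i] + 1L
            hi <- stops[i]
            if (hi - lo < min_aa) next      # interval too short even in principle
            atg_in <- which(is_atg[lo:(hi - 1L)])
            if (!length(atg_in)) next
            # anchor at the interval's first ATG whose span fits the genome
            # (an ORF cannot be longer than the circle it sits on)
            atg_in <- atg_in[hi - (lo + atg_in - 1L) <= max_aa]
            if (!length(atg_in)) next
            i0 <- lo + atg_in[1L] - 1L
            len_aa <- hi - i0
            if (len_aa < min_aa) next
            # reject candidates containing an ambiguity code in any codon
            n_in_span <- csum_n[hi] - if (i0 > 1L) csum_n[i0 - 1L] else 0L
            if (n_in_span > 0L) next
            res[[length(res) + 1L]] <- c(start = p[i0], end = p[hi] + 2L,
                                         frame = f, length_aa = len_aa,
                                         left_stop = if (bounds[i] > 0L) p[bounds[i]] else 0L)
        }
        out[[f + 1L]] <- res
    }
    res_all <- unlist(out, recursive = FALSE)
    m <- if (length(res_all)) do.call(rbind, res_all) else NULL
    if (is.null(m)) {
        data.frame(start = integer(), end = integer(), frame = integer(),
                   length_aa = integer(), left_stop = integer())
    } else {
        as.data.frame(m)
    }
}

#' Find candidate ORFs in all six frames
#'
#' Each stop-to-stop interval of each strand and frame contributes at most one
#' candidate, anchored at its first ATG, provided it encodes at least
#' \code{min_aa} amino acids and ends at a stop codon.  On a circular genome
#' candidates spanning the origin are found by scanning the doubled sequence.
#' Candidates whose span contains an N in any codon are rejected.
#'
#' @param genome a \code{\link{circular_genome}}.
#' @param min_aa minimum protein length in amino acids (initiator Met counted,
#'   stop excluded); default 50.
#' @return a data frame of class \code{orf_candidates} with columns
#'   \code{start}, \code{end} (1-based inclusive plus-strand coordinates, stop
#'   codon included; \code{start > end} with \code{wrap = TRUE} for
#'   origin-wrapping candidates), \code{strand}, \code{frame} (0-2 per
#'   strand), \code{length_aa}, \code{wrap}; sorted by start.
#' @export
find_candidate_orfs <- function(genome, min_aa = 50L) {
    stopifnot(inherits(genome, "circular_genome"), min_aa >= 1L)
    L <- genome$length
    if (L < 3L) stop("genome shorter than one codon")
    # On a circle whose length is not a multiple of 3 the three reading frames
    # of one strand merge into a single cyclic orbit of L codons with period
    # 3L nt; when L is divisible by 3 each frame is its own orbit of period L.
    # Scanning two full orbit periods guarantees that every stop-to-stop arc
    # (arcs are at most one orbit long) appears contiguously, with a genuine
    # left-bounding stop, in at least one linear frame.  Arcs recur across
    # frames and copies; mapping coordinates modulo L and deduplicating keeps
    # each arc exactly once.
    wrapped <- genome$circular && L >= 6L
    n_copies <- if (L %% 3L == 0L) 2L else 6L
    # two more characters so that an arc spanning a whole cyclic frame (one
    # single stop codon bounding the entire circle) still closes: its
    # terminal stop begins exactly one orbit period after the left stop
    s_plus <- if (wrapped) {
        paste0(strrep(genome$sequence, n_copies), substring(genome$sequence, 1L, 2L))
    } else {
        genome$sequence
    }
    rows <- list()
    for (strand in c("+", "-")) {
        s <- if (strand == "+") s_plus else revcomp(s_plus)
        cand <- .scan_frames(s, min_aa, require_left_stop = wrapped,
                             max_aa = if (wrapped) (L - 3L) %/% 3L else Inf)
        if (!nrow(cand)) next
        if (wrapped) {
            cand <- cand[(cand$end - cand$start + 1L) <= L, , drop = FALSE]
        }
        if (!nrow(cand)) next
        if (strand == "+") {
            p5 <- cand$start
            p3 <- cand$end
        } else {
            # map positions in the reverse-complemented string back to the
            # plus strand of the (possibly tripled) sequence
            n2 <- nchar(s)
            p5 <- n2 - cand$end + 1L
            p3 <- n2 - cand$start + 1L
        }
        p1 <- ((p5 - 1L) %% L) + 1L
        p2 <- ((p3 - 1L) %% L) + 1L
        rows[[strand]] <- data.frame(start = p1, end = p2, strand = strand,
                                     frame = (p1 - 1L) %% 3L,
                                     length_aa = cand$length_aa,
                                     wrap = p1 > p2)
    }
    out <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE)) else {
        data.frame(start = integer(), end = integer(), strand = character(),
                   frame = integer(), length_aa = integer(), wrap = logical())
    }
    out <- unique(out)
    out <- out[order(out$start, out$end, out$strand), , drop = FALSE]
    rownames(out) <- NULL
    class(out) <- c("orf_candidates", "data.frame")
    attr(out, "genome_length") <- L
    out
}

# inclusive-span intervals of a feature on the (possibly circular) genome,
# as a 2-column matrix of linear pieces
.span_pieces <- function(start, end, wrap, L) {
    if (wrap) rbind(c(start, L), c(1L, end)) else rbind(c(start, end))
}

# pairwise inclusive-span overlap in nucleotides
.span_overlap <- function(s1, e1, w1, s2, e2, w2, L) {
    a <- .span_pieces(s1, e1, w1, L)
    b <- .span_pieces(s2, e2, w2, L)
    tot <- 0L
    for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
        ov <- min(a[i, 2L], b[j, 2L]) - max(a[i, 1L], b[j, 1L]) + 1L
        if (ov > 0L) tot <- tot + ov
    }
    tot
}

#' Resolve candidates to a minimal-overlap ORF set
#'
#' Greedy selection in decreasing protein-length order: a candidate is kept
#' iff its inclusive-span intersection with every already-kept ORF is at most
#' \code{max_overlap_nt} and it is not fully nested inside a kept ORF.  Kept
#' ORFs are re-sorted by start and re-indexed from 1.
#'
#' @param candidates an \code{orf_candidates} data frame from
#'   \code{\link{find_candidate_orfs}}.
#' @param max_overlap_nt largest tolerated pairwise overlap (default 250 nt).
#' @param genome_length required when not carried by \code{candidates}.
#' @return a data frame of ORF records (\code{index}, \code{name},
#'   \code{start}, \code{end}, \code{strand}, \code{length_aa},
#'   \code{promoter_class = "unassigned"}, \code{wrap}).
#' @export
resolve_minimal_overlap <- function(candidates, max_overlap_nt = 250L,
                                    genome_length = attr(candidates, "genome_length")) {
    cand <- as.data.frame(candidates)
    if (!nrow(cand)) {
        return(data.frame(index = integer(), name = character(), start = integer(),
                          end = integer(), strand = character(), length_aa = integer(),
                          promoter_class = character(), wrap = logical()))
    }
    if (is.null(genome_length)) stop("genome_length required")
    # deterministic processing order, independent of input order
    cand <- cand[order(-cand$length_aa, cand$start, cand$end, cand$strand), , drop = FALSE]
    span <- orf_span_nt(cand$start, cand$end, cand$wrap, genome_length)
    kept <- integer()
    for (i in seq_len(nrow(cand))) {
        ok <- TRUE
        for (k in kept) {
            ov <- .span_overlap(cand$start[i], cand$end[i], cand$wrap[i],
                                cand$start[k], cand$end[k], cand$wrap[k], genome_length)
            if (ov > max_overlap_nt || ov == span[i]) { ok <- FALSE; break }
        }
        if (ok) kept <- c(kept, i)
    }
    out <- cand[kept, , drop = FALSE]
    out <- out[order(out$start, out$end), , drop = FALSE]
    data.frame(index = seq_len(nrow(out)), name = "", start = out$start,
               end = out$end, strand = out$strand, length_aa = out$length_aa,
               promoter_class = "unassigned", wrap = out$wrap)
}

# extract the (possibly wrapping) span sequence on the coding strand
orf_sequence <- function(genome, start, end, strand = "+", wrap = start > end) {
    s <- if (wrap) {
        paste0(substring(genome$sequence, start, genome$length),
               substring(genome$sequence, 1L, end))
    } else {
        substring(genome$sequence, start, end)
    }
    if (strand == "-") revcomp(s) else s
}

#' Translate an ORF
#'
#' @param genome a \code{\link{circular_genome}}.
#' @param orf a one-row data frame (or list) with \code{start}, \code{end},
#'   \code{strand} and optionally \code{wrap}.
#' @return the protein string (standard genetic code), terminal stop removed.
#'   Reverse-strand ORFs are translated from the reverse complement.
#' @export
translate_orf <- function(genome, orf) {
    wrap <- if (!is.null(orf$wrap)) isTRUE(orf$wrap) else orf$start > orf$end
    nt <- orf_sequence(genome, orf$start, orf$end, orf$strand, wrap)
    if (nchar(nt) < 6L) stop("ORF span shorter than 6 nt")
    if (nchar(nt) %% 3L != 0L) stop("ORF span not divisible by 3")
    codons <- substring(nt, seq(1L, nchar(nt), 3L), seq(3L, nchar(nt), 3L))
    aa <- Biostrings::GENETIC_CODE[codons]
    if (anyNA(aa)) stop("untranslatable codon (ambiguity code?) in ORF")
    if (aa[length(aa)] == "*") aa <- aa[-length(aa)]
    paste(aa, collapse = "")
}

#' Annotate a genome end to end
#'
#' Convenience wrapper: candidate scan, minimal-overlap resolution, and
#' packaging as an \code{\link{annotation_set}}.
#'
#' @inheritParams find_candidate_orfs
#' @inheritParams resolve_minimal_overlap
#' @return an \code{\link{annotation_set}}.
#' @export
annotate_genome <- function(genome, min_aa = 50L, max_overlap_nt = 250L) {
    cand <- find_candidate_orfs(genome, min_aa = min_aa)
    orfs <- resolve_minimal_overlap(cand, max_overlap_nt = max_overlap_nt,
                                    genome_length = genome$length)
    annotation_set(genome$id, genome$length, orfs)
}
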