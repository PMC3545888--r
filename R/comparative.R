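# Pairwise proteome comparison, identity-gene-parity analysis, segmental
# indel detection, and transposon-signature scanning.

.AA_ALPHABET <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q",
                  "R","S","T","V","W","Y","X","*")

.aa_codes <- function(x, what) {
    v <- .as_bases(x)
    m <- match(v, .AA_ALPHABET)
    if (anyNA(m)) {
        stop("non-amino-acid character in ", what, ": ",
             paste(unique(v[is.na(m)]), collapse = ", "))
    }
    m
}

#' Global alignment with percent identity
#'
#' Needleman-Wunsch global alignment under a simple identity scoring scheme
#' (match +1, mismatch 0, gap -1 per column by default) with a deterministic
#' traceback (tie-break: diagonal, then up, then left).  Percent identity is
#' computed over all alignment columns, gap columns included.
#'
#' @param prot_a,prot_b protein sequences (upper-case one-letter code; X
#'   allowed).
#' @param match,mismatch,gap scoring parameters.
#' @return a list of class \code{alignment_result}: \code{aligned_length},
#'   \code{identities}, \code{pct_identity}, \code{score}.
#' @export
align_global_identity <- function(prot_a, prot_b, match = 1, mismatch = 0, gap = -1) {
    stopifnot(nzchar(prot_a), nzchar(prot_b))
    r <- nw_align_cpp(.aa_codes(prot_a, "prot_a"), .aa_codes(prot_b, "prot_b"),
                      match, mismatch, gap)
    structure(list(aligned_length = r$aligned_length, identities = r$identities,
                   pct_identity = 100 * r$identities / r$aligned_length,
                   score = r$score),
              class = "alignment_result")
}

#' Map homologs between two proteomes by reciprocal best hit
#'
#' All-against-all global identity; a pair is reported when each member is
#' the other's best hit by percent identity (ties broken by alignment score,
#' then by lower partner index) and the identity is at least \code{min_pct}.
#'
#' @param proteome_a,proteome_b character vectors of protein sequences,
#'   indexed by ORF order.
#' @param min_pct minimum percent identity for a reported pair (default 15).
#' @return data frame with \code{index_a}, \code{index_b},
#'   \code{pct_identity}, \code{score}.
#' @export
map_homologs <- function(proteome_a, proteome_b, min_pct = 15) {
    na <- length(proteome_a); nb <- length(proteome_b)
    empty <- data.frame(index_a = integer(), index_b = integer(),
                        pct_identity = numeric(), score = numeric())
    if (na == 0L || nb == 0L) return(empty)
    ca <- lapply(proteome_a, .aa_codes, what = "proteome_a")
    cb <- lapply(proteome_b, .aa_codes, what = "proteome_b")
    pid <- matrix(0, na, nb); sco <- matrix(-Inf, na, nb)
    for (i in seq_len(na)) for (j in seq_len(nb)) {
        r <- nw_align_cpp(ca[[i]], cb[[j]], 1, 0, -1)
        pid[i, j] <- 100 * r$identities / r$aligned_length
        sco[i, j] <- r$score
    }
    best_of <- function(p, s) {          # best index with deterministic ties
        cand <- which(p == max(p))
        cand <- cand[s[cand] == max(s[cand])]
        cand[1L]
    }
    best_a <- vapply(seq_len(na), function(i) best_of(pid[i, ], sco[i, ]), 0L)
    best_b <- vapply(seq_len(nb), function(j) best_of(pid[, j], sco[, j]), 0L)
    recip <- which(best_b[best_a] == seq_len(na))
    out <- data.frame(index_a = recip, index_b = best_a[recip],
                      pct_identity = pid[cbind(recip, best_a[recip])],
                      score = sco[cbind(recip, best_a[recip])])
    out <- out[out$pct_identity >= min_pct, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Build identity-gene-parity data
#'
#' Shared ORFs become points at (rank in genome A, rank in genome B) with an
#' identity bin; ORFs without a partner are listed as unique to their genome
#' (plotted on the axes of a parity plot).
#'
#' @param pairs data frame with \code{index_a}, \code{index_b},
#'   \code{pct_identity} (e.g. from \code{\link{map_homologs}}).
#' @param n_a,n_b ORF counts of the two genomes.
#' @param bins identity cut points for binning (default 30, 50, 70).
#' @return a list of class \code{parity_data}: \code{points} (rank_a, rank_b,
#'   pct_identity, identity_bin), \code{unique_a}, \code{unique_b},
#'   \code{n_a}, \code{n_b}.
#' @export
gene_parity <- function(pairs, n_a, n_b, bins = c(30, 50, 70)) {
    if (anyDuplicated(pairs$index_a)) {
        stop("duplicate pairing of an ORF in parity input")
    }
    # duplicated partners on the B side are tolerated: curated homolog tables
    # occasionally map two query ORFs onto one subject ORF
    if (nrow(pairs) &&
        (any(pairs$index_a < 1 | pairs$index_a > n_a) ||
         any(pairs$index_b < 1 | pairs$index_b > n_b))) {
        stop("pair index outside genome ORF range")
    }
    brk <- c(-Inf, bins, Inf)
    lab <- c(paste0("<", bins[1L]),
             paste0(bins[-length(bins)], "-", bins[-1L]),
             paste0(">=", bins[length(bins)]))
    points <- data.frame(rank_a = pairs$index_a, rank_b = pairs$index_b,
                         pct_identity = pairs$pct_identity,
                         identity_bin = as.character(cut(pairs$pct_identity, brk,
                                                         labels = lab, right = FALSE)))
    points <- points[order(points$rank_a), , drop = FALSE]
    rownames(points) <- NULL
    structure(list(points = points,
                   unique_a = setdiff(seq_len(n_a), pairs$index_a),
                   unique_b = setdiff(seq_len(n_b), pairs$index_b),
                   n_a = n_a, n_b = n_b),
              class = "parity_data")
}

#' Collinearity statistics of a parity data set
#'
#' @param parity a \code{parity_data} object.
#' @return list with \code{rank_correlation} (Spearman on the point ranks; NA
#'   with fewer than 2 points), \code{n_shared}, \code{n_unique_a},
#'   \code{n_unique_b}, and \code{adjacency_preserved_fraction} (fraction of
#'   point pairs consecutive in genome-A order that are also consecutive in
#'   genome-B order).
#' @export
collinearity_stats <- function(parity) {
    p <- parity$points
    n <- nrow(p)
    rho <- if (n >= 2L) cor(p$rank_a, p$rank_b, method = "spearman") else NA_real_
    adj <- if (n >= 2L) {
        ord_b <- rank(p$rank_b)             # position of each point in B order
        mean(abs(diff(ord_b[order(p$rank_a)])) == 1)
    } else NA_real_
    list(rank_correlation = rho, n_shared = n,
         n_unique_a = length(parity$unique_a), n_unique_b = length(parity$unique_b),
         adjacency_preserved_fraction = adj)
}

#' Detect segmental indels between two gene orders
#'
#' Maximal runs of at least \code{min_run} consecutive ORFs of one genome
#' with no homolog in the other, flanked by paired ORFs; a missing flank at a
#' genome end is reported as "terminal".
#'
#' @param pairs homolog pairs (\code{index_a}, \code{index_b}).
#' @param order_a,order_b ORF index vectors of the two genomes in genomic
#'   order.
#' @param min_run minimum run length (default 2).
#' @param ann_a,ann_b optional \code{\link{annotation_set}}s supplying the
#'   nucleotide extent of each run.
#' @return data frame with \code{genome} ("A"/"B"), \code{first_orf},
#'   \code{last_orf}, \code{n_orfs}, \code{flank_left}, \code{flank_right}
#'   (ORF index or "terminal"), and nt extent columns when annotation given.
#' @export
detect_segmental_indels <- function(pairs, order_a, order_b, min_run = 2L,
                                    ann_a = NULL, ann_b = NULL) {
    scan_one <- function(ord, paired, genome, ann) {
        un <- !(ord %in% paired)
        if (!any(un)) return(NULL)
        r <- rle(un)
        stops <- cumsum(r$lengths)
        starts <- stops - r$lengths + 1L
        rows <- list()
        for (k in which(r$values & r$lengths >= min_run)) {
            i0 <- starts[k]; i1 <- stops[k]
            run <- ord[i0:i1]
            fl <- if (i0 > 1L) as.character(ord[i0 - 1L]) else "terminal"
            fr <- if (i1 < length(ord)) as.character(ord[i1 + 1L]) else "terminal"
            row <- data.frame(genome = genome, first_orf = run[1L],
                              last_orf = run[length(run)], n_orfs = length(run),
                              flank_left = fl, flank_right = fr,
                              nt_start = NA_integer_, nt_end = NA_integer_)
            if (!is.null(ann)) {
                o <- ann$orfs[ann$orfs$index %in% run, , drop = FALSE]
                row$nt_start <- min(o$start); row$nt_end <- max(o$end)
            }
            rows[[length(rows) + 1L]] <- row
        }
        do.call(rbind, c(rows, make.row.names = FALSE))
    }
    out <- rbind(scan_one(order_a, pairs$index_a, "A", ann_a),
                 scan_one(order_b, pairs$index_b, "B", ann_b))
    if (is.null(out)) {
        out <- data.frame(genome = character(), first_orf = integer(),
                          last_orf = integer(), n_orfs = integer(),
                          flank_left = character(), flank_right = character(),
                          nt_start = integer(), nt_end = integer())
    }
    out
}

#' Scan for transposon insertion signatures
#'
#' Finds all position pairs (i, j) inside a region where the \code{itr_len}
#' bases starting at i equal the reverse complement of the \code{itr_len}
#' bases ending at j (perfect inverted terminal repeats), with the target-site
#' duplication \code{tsd} immediately 5' of i and immediately 3' of j, and the
#' element span at most \code{max_span}.
#'
#' @param genome a \code{\link{circular_genome}}.
#' @param region_start,region_end region to scan (1-based inclusive,
#'   non-wrapping).
#' @param itr_len inverted-terminal-repeat length (at least 4; default 13).
#' @param tsd expected target-site duplication (default "TTAA").
#' @param max_span maximum element span in nt (default: region length).
#' @return data frame with \code{element_start}, \code{element_end},
#'   \code{itr_seq}, \code{itr_len}, \code{tsd}, \code{left_tsd_pos},
#'   \code{right_tsd_pos}.
#' @export
scan_transposon_signature <- function(genome, region_start = 1L,
                                      region_end = genome$length,
                                      itr_len = 13L, tsd = "TTAA",
                                      max_span = region_end - region_start + 1L) {
    if (itr_len < 4L) stop("itr_len must be at least 4")
    stopifnot(region_start >= 1L, region_end <= genome$length,
              region_start <= region_end)
    seq <- genome$sequence
    tl <- nchar(tsd)
    empty <- data.frame(element_start = integer(), element_end = integer(),
                        itr_seq = character(), itr_len = integer(), tsd = character(),
                        left_tsd_pos = integer(), right_tsd_pos = integer())
    # candidate left edges: i with tsd ending at i-1; right edges: j with tsd
    # starting at j+1 (tsd occurrences constrained to the region's vicinity)
    tsd_pos <- .match_starts(substring(seq, max(1L, region_start - tl), region_end + min(tl, genome$length - region_end)),
                             .iupac_regex(tsd)) + max(1L, region_start - tl) - 1L
    lefts <- tsd_pos + tl
    rights <- tsd_pos - 1L
    lefts <- lefts[lefts >= region_start & lefts + itr_len - 1L <= region_end]
    rights <- rights[rights <= region_end & rights - itr_len + 1L >= region_start]
    if (!length(lefts) || !length(rights)) return(empty)
    rows <- list()
    for (i in lefts) {
        itr <- substring(seq, i, i + itr_len - 1L)
        itr_rc <- revcomp(itr)
        for (j in rights) {
            if (j <= i + itr_len - 1L) next          # ITRs must not overlap
            if (j - i + 1L > max_span) next
            if (substring(seq, j - itr_len + 1L, j) == itr_rc) {
                rows[[length(rows) + 1L]] <- data.frame(
                    element_start = i, element_end = j, itr_seq = itr,
                    itr_len = itr_len, tsd = tsd,
                    left_tsd_pos = i - tl, right_tsd_pos = j + 1L)
            }
        }
    }
    if (!length(rows)) return(empty)
    do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Shared-gene count and mean identity for one comparison virus
#'
#' @param ann an \code{\link{annotation_set}} with homolog columns.
#' @param virus name of a comparison virus present in the annotation.
#' @return list with \code{n_shared} and \code{mean_pct_identity} (rounded to
#'   one decimal, as identity tables conventionally print it).
#' @export
summary_identities <- function(ann, virus) {
    stopifnot(inherits(ann, "annotation_set"))
    if (!(virus %in% ann$viruses)) {
        stop("unknown virus '", virus, "'; available: ",
             paste(ann$viruses, collapse = ", "))
    }
    h <- ann$homologs[ann$homologs$virus == virus, , drop = FALSE]
    list(n_shared = nrow(h),
         mean_pct_identity = round(mean(h$pct_identity), 1L))
}
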