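# Independent brute-force oracles and small random-input generators.
# These deliberately re-derive each quantity from first principles (per-position
# walks, exhaustive window scans, explicit enumeration) so they share no code
# path with the package implementation.

rand_dna <- function(n, p = c(0.25, 0.25, 0.25, 0.25)) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p), collapse = "")
}

rand_prot <- function(n) {
    paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
          collapse = "")
}

.o_revcomp <- function(x) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
}

# brute-force ORF finder: try every (position, strand) as an ATG, walk codons
# (cyclically if circular) to the stop, then keep the longest candidate per
# terminal stop (= the interval's first ATG)
oracle_orfs <- function(seq, circular = TRUE, min_aa = 50L) {
    L <- nchar(seq)
    stops <- c("TAA", "TAG", "TGA")
    res <- list()
    for (strand in c("+", "-")) {
        s <- if (strand == "+") seq else .o_revcomp(seq)
        ext <- if (circular) paste0(s, s) else s
        v <- strsplit(ext, "")[[1]]
        for (i in seq_len(L)) {
            if (!circular && i + 2L > L) next
            cod <- paste(v[i:(i + 2L)], collapse = "")
            if (cod != "ATG") next
            len <- 0L; stop_at <- NA_integer_; bad_n <- FALSE
            j <- i
            repeat {
                if (!circular && j + 2L > L) break
                if (circular && (j - i) >= L) break
                cj <- paste(v[j:(j + 2L)], collapse = "")
                if (grepl("N", cj)) bad_n <- TRUE
                if (cj %in% stops) { stop_at <- j; break }
                len <- len + 1L
                j <- j + 3L
            }
            if (is.na(stop_at) || bad_n || len < min_aa) next
            res[[length(res) + 1L]] <- data.frame(
                strand = strand, atg = i, stop = stop_at, length_aa = len)
        }
    }
    if (!length(res)) {
        return(data.frame(start = integer(), end = integer(), strand = character(),
                          length_aa = integer(), wrap = logical()))
    }
    d <- do.call(rbind, res)
    # spans cannot exceed the genome: such ATGs are no anchors at all
    d <- d[3L * (d$length_aa + 1L) <= L | !circular, , drop = FALSE]
    # one candidate per (strand, cyclic stop): the longest remaining
    # (= the arc's first ATG whose span fits)
    d$stop_key <- paste(d$strand, if (circular) ((d$stop - 1L) %% L) + 1L else d$stop)
    d <- d[order(-d$length_aa, d$atg), ]
    d <- d[!duplicated(d$stop_key), ]
    # and each cyclic ATG only once
    d$atg_key <- paste(d$strand, if (circular) ((d$atg - 1L) %% L) + 1L else d$atg)
    d <- d[!duplicated(d$atg_key), ]
    if (!nrow(d)) {
        return(data.frame(start = integer(), end = integer(), strand = character(),
                          length_aa = integer(), wrap = logical()))
    }
    out <- do.call(rbind, lapply(seq_len(nrow(d)), function(k) {
        span <- 3L * (d$length_aa[k] + 1L)
        a <- d$atg[k]
        if (d$strand[k] == "+") {
            lo <- a; hi <- a + span - 1L
        } else {
            n2 <- if (circular) 2L * L else L
            hi <- n2 - a + 1L
            lo <- hi - span + 1L
        }
        p1 <- ((lo - 1L) %% L) + 1L
        p2 <- ((hi - 1L) %% L) + 1L
        data.frame(start = p1, end = p2, strand = d$strand[k],
                   length_aa = d$length_aa[k], wrap = p2 < p1)
    }))
    out <- unique(out)
    out[order(out$start, out$end, out$strand), , drop = FALSE]
}

# exhaustive all-windows palindrome scan with the same merge rule, written
# against the raw definition
oracle_palindromes <- function(seq, unit_len, max_arm_mismatch, circular = TRUE) {
    L <- nchar(seq)
    arm <- unit_len %/% 2L
    ext <- if (circular) paste0(seq, substring(seq, 1L, unit_len - 1L)) else seq
    v <- strsplit(ext, "")[[1]]
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "?")
    n_win <- length(v) - unit_len + 1L
    hits <- integer(); mms <- integer()
    for (i in seq_len(max(0L, n_win))) {
        if (i > L) break
        w <- v[i:(i + unit_len - 1L)]
        mm <- 0L
        for (k in seq_len(arm)) {
            if (w[k] == "N" || w[unit_len - k + 1L] == "N" ||
                w[k] != comp[[w[unit_len - k + 1L]]]) mm <- mm + 1L
        }
        if (mm <= max_arm_mismatch) { hits <- c(hits, i); mms <- c(mms, mm) }
    }
    if (!length(hits)) {
        return(data.frame(start = integer(), mismatches = integer()))
    }
    grp <- cumsum(c(1L, as.integer(diff(hits) > unit_len %/% 2L)))
    keep <- vapply(split(seq_along(hits), grp), function(ix) {
        centre <- min(hits[ix]) + max(hits[ix])
        ix[order(mms[ix], abs(2L * hits[ix] - centre), hits[ix])[1L]]
    }, 0L)
    data.frame(start = hits[keep], mismatches = 2L * mms[keep])
}

# exhaustive (i, j) pair enumeration for the ITR/TSD signature
oracle_transposon <- function(seq, region_start, region_end, itr_len, tsd,
                              max_span) {
    L <- nchar(seq)
    tl <- nchar(tsd)
    out <- list()
    for (i in region_start:region_end) {
        if (i - tl < 1L || i + itr_len - 1L > region_end) next
        if (substring(seq, i - tl, i - 1L) != tsd) next
        itr <- substring(seq, i, i + itr_len - 1L)
        for (j in region_start:region_end) {
            if (j <= i + itr_len - 1L) next
            if (j - i + 1L > max_span) next
            if (j + tl > L || j - itr_len + 1L < region_start) next
            if (substring(seq, j + 1L, j + tl) != tsd) next
            if (substring(seq, j - itr_len + 1L, j) == .o_revcomp(itr)) {
                out[[length(out) + 1L]] <- c(i, j)
            }
        }
    }
    if (!length(out)) return(data.frame(element_start = integer(), element_end = integer()))
    m <- do.call(rbind, out)
    data.frame(element_start = m[, 1], element_end = m[, 2])
}

# exhaustive global-alignment score by enumeration over all non-crossing
# matchings (each a_i either gapped or matched to some b_k), no DP matrix
oracle_align_score <- function(a, b, match = 1, mismatch = 0, gap = -1) {
    av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
    n <- length(av); m <- length(bv)
    rec <- function(i, j) {
        if (i > n) return(gap * (m - j + 1L))
        best <- gap + rec(i + 1L, j)          # a_i unmatched
        if (j <= m) {
            for (k in j:m) {                  # a_i matched to b_k
                sc <- gap * (k - j) +
                    (if (av[i] == bv[k]) match else mismatch) +
                    rec(i + 1L, k + 1L)
                if (sc > best) best <- sc
            }
        }
        best
    }
    rec(1L, 1L)
}

# direct-formula Spearman correlation (distinct ranks)
oracle_spearman <- function(x, y) {
    n <- length(x)
    d <- rank(x) - rank(y)
    1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

as_genome <- function(seq, circular = TRUE, id = "t") {
    circular_genome(id, seq, circular = circular)
}

# canonical comparable form of an ORF table
orf_key <- function(d) {
    d <- as.data.frame(d)[c("start", "end", "strand", "length_aa")]
    d <- d[order(d$start, d$end, d$strand), , drop = FALSE]
    rownames(d) <- NULL
    d
}
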