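# Homologous-region (hr) detection.
#
# hrs are modelled as clusters of ~40-bp near-palindromic units (type A) with
# 31-bp direct-repeat flanks (type B), sitting in AT-rich intergenic sequence.
# Type A units are found by an arm-vs-reverse-complement mismatch scan; type B
# units by matching flank segments against a consensus built greedily from all
# candidate flanks; regions are single-linkage clusters of units.

#' Find near-palindromic repeat units (type A)
#'
#' Every window of \code{unit_len} whose left arm matches the reverse
#' complement of its right arm with at most \code{max_arm_mismatch}
#' mismatches.  Overlapping hits whose starts lie within \code{unit_len/2} of
#' each other are merged, keeping the fewest-mismatch window (ties: leftmost).
#'
#' @param genome a \code{\link{circular_genome}}.
#' @param unit_len palindrome length in nt (even, at least 8; default 40).
#' @param max_arm_mismatch per-arm mismatch tolerance (default 3).
#' @return data frame of type-A units: \code{unit_type}, \code{start},
#'   \code{end}, \code{orientation}, \code{mismatches} (Hamming distance of
#'   the unit to its own reverse complement, i.e. twice the arm count).
#' @export
find_palindromes <- function(genome, unit_len = 40L, max_arm_mismatch = 3L) {
    stopifnot(inherits(genome, "circular_genome"),
              unit_len %% 2L == 0L, unit_len >= 8L)
    L <- genome$length
    empty <- data.frame(unit_type = character(), start = integer(), end = integer(),
                        orientation = character(), mismatches = integer())
    if (unit_len > L) return(empty)
    arm <- unit_len %/% 2L
    v <- .as_bases(genome$sequence)
    cv <- .comp_vec(v)
    if (genome$circular) { v <- c(v, v[seq_len(unit_len - 1L)]); cv <- c(cv, cv[seq_len(unit_len - 1L)]) }
    n_win <- length(v) - unit_len + 1L
    if (n_win < 1L) return(empty)
    idx <- seq_len(n_win)
    mm <- integer(n_win)
    for (k in seq_len(arm)) {
        # position k of the left arm pairs with position unit_len - k + 1
        neq <- v[idx + k - 1L] != cv[idx + unit_len - k]
        # windows containing N never match (N pairs with nothing)
        neq <- neq | v[idx + k - 1L] == "N" | v[idx + unit_len - k] == "N"
        mm <- mm + as.integer(neq)
    }
    hit <- which(mm <= max_arm_mismatch)
    hit <- hit[hit <= L]                    # one copy per circular position
    if (!length(hit)) return(empty)
    # merge clusters of nearby windows; keep the fewest-mismatch window, ties
    # broken by closeness to the cluster centre (a reversal-symmetric rule,
    # so the reported set is invariant under reverse-complementing), then by
    # position
    d <- diff(hit)
    grp <- cumsum(c(1L, as.integer(d > unit_len %/% 2L)))
    keep <- vapply(split(seq_along(hit), grp), function(ix) {
        centre <- min(hit[ix]) + max(hit[ix])
        score <- order(mm[hit[ix]], abs(2L * hit[ix] - centre), hit[ix])[1L]
        ix[score]
    }, 0L)
    starts <- hit[keep]
    data.frame(unit_type = "A", start = starts,
               end = ((starts + unit_len - 2L) %% L) + 1L,
               orientation = "forward", mismatches = 2L * mm[starts],
               row.names = NULL)
}

# mismatch counts of every `len`-window of base vector v against consensus cb
.window_mismatches <- function(v, cb) {
    len <- length(cb)
    n_win <- length(v) - len + 1L
    if (n_win < 1L) return(integer())
    mm <- integer(n_win)
    idx <- seq_len(n_win)
    for (k in seq_len(len)) mm <- mm + as.integer(v[idx + k - 1L] != cb[k])
    mm
}

#' Find direct-repeat flank units (type B)
#'
#' Searches, within \code{search_radius} of each type-A unit, for
#' \code{unit_len}-nt segments matching the genome-wide type-B consensus with
#' at most \code{max_mismatch} mismatches; at most one B unit per side per A
#' unit.  The consensus is built greedily: the most frequent candidate k-mer
#' seeds it, and one round of per-column majority voting over the best match
#' per flank refines it.
#'
#' @param genome a \code{\link{circular_genome}}.
#' @param palindromes type-A units from \code{\link{find_palindromes}}.
#' @param unit_len flank-repeat length in nt (default 31).
#' @param max_mismatch tolerated mismatches against the consensus (default 4).
#' @param search_radius how far beyond each A-unit boundary to look (default
#'   100 nt).
#' @return data frame of type-B units (\code{unit_type}, \code{start},
#'   \code{end}, \code{orientation}, \code{mismatches}, \code{side},
#'   \code{a_start} of the anchoring A unit); attribute \code{consensus}
#'   carries the consensus string.
#' @export
find_flank_repeats <- function(genome, palindromes, unit_len = 31L,
                               max_mismatch = 4L, search_radius = 100L) {
    empty <- data.frame(unit_type = character(), start = integer(), end = integer(),
                        orientation = character(), mismatches = integer(),
                        side = character(), a_start = integer())
    if (is.null(palindromes) || nrow(palindromes) == 0L) return(empty)
    L <- genome$length
    v <- .as_bases(genome$sequence)
    # flank candidate windows per A unit and side (clipped at genome ends).
    # A flank segment may not overlap ANY palindromic unit - neighbouring A
    # units can fall inside the search radius, and a window dipping into one
    # would let the palindrome sequence itself masquerade as a flank repeat.
    win_ok <- function(starts) {
        ok <- rep(TRUE, length(starts))
        for (k in seq_len(nrow(palindromes))) {
            ok <- ok & (starts + unit_len - 1L < palindromes$start[k] |
                        starts > palindromes$end[k])
        }
        ok
    }
    flanks <- list()
    for (i in seq_len(nrow(palindromes))) {
        a <- palindromes[i, ]
        lo <- max(1L, a$start - search_radius - unit_len)
        if (a$start - 1L - lo + 1L >= unit_len) {
            flanks[[length(flanks) + 1L]] <-
                list(from = lo, to = a$start - 1L, side = "left", a_start = a$start)
        }
        hi <- min(L, a$end + search_radius + unit_len)
        if (hi - (a$end + 1L) + 1L >= unit_len) {
            flanks[[length(flanks) + 1L]] <-
                list(from = a$end + 1L, to = hi, side = "right", a_start = a$start)
        }
    }
    if (!length(flanks)) return(empty)
    # seed consensus: most frequent k-mer over all admissible windows
    kmers <- unlist(lapply(flanks, function(f) {
        n <- f$to - f$from + 1L - unit_len + 1L
        if (n < 1L) return(character())
        starts <- (f$from + seq_len(n) - 1L)[win_ok(f$from + seq_len(n) - 1L)]
        if (!length(starts)) return(character())
        substring(genome$sequence, starts, starts + unit_len - 1L)
    }))
    if (!length(kmers)) return(empty)
    best_per_flank <- function(cons_b) {
        do.call(rbind, lapply(flanks, function(f) {
            w <- v[f$from:f$to]
            mm <- .window_mismatches(w, cons_b)
            if (!length(mm)) return(NULL)
            starts <- f$from + seq_along(mm) - 1L
            mm[!win_ok(starts)] <- NA_integer_
            if (all(is.na(mm))) return(NULL)
            j <- which.min(mm)
            data.frame(start = starts[j], mismatches = mm[j],
                       side = f$side, a_start = f$a_start)
        }))
    }
    # seed: among the most frequent candidate k-mers, the one that accepts
    # the most flanks, with ties broken by the tightest total mismatch (this
    # keeps the consensus in phase with the repeat rather than one column
    # off) and then by frequency rank
    tab <- sort(table(kmers), decreasing = TRUE)
    seeds <- names(tab)[seq_len(min(length(tab), 30L))]
    seeds <- seeds[order(-as.integer(tab[seeds]), seeds)]
    stats <- vapply(seeds, function(sd) {
        h <- best_per_flank(.as_bases(sd))
        acc <- h$mismatches <= max_mismatch
        c(sum(acc), sum(h$mismatches[acc]))
    }, numeric(2L))
    seed <- seeds[order(-stats[1L, ], stats[2L, ], seq_along(seeds))][1L]
    cons_b <- .as_bases(seed)
    hits <- best_per_flank(cons_b)
    good <- hits[hits$mismatches <= max_mismatch, , drop = FALSE]
    if (nrow(good) >= 2L) {
        # one majority-vote refinement over the accepted flanks
        mat <- do.call(rbind, lapply(good$start, function(s) v[s:(s + unit_len - 1L)]))
        cons_b <- apply(mat, 2L, function(col) {
            t <- table(col); sort(names(t)[t == max(t)])[1L]
        })
        hits <- best_per_flank(cons_b)
    }
    out <- hits[hits$mismatches <= max_mismatch, , drop = FALSE]
    # a lone matching segment is its own trivial consensus, not a repeat
    if (nrow(out) < 2L) return(`attr<-`(empty, "consensus", paste(cons_b, collapse = "")))
    res <- data.frame(unit_type = "B", start = out$start,
                      end = out$start + unit_len - 1L, orientation = "forward",
                      mismatches = out$mismatches, side = out$side,
                      a_start = out$a_start, row.names = NULL)
    res <- res[!duplicated(res[c("start", "end")]), , drop = FALSE]
    rownames(res) <- NULL
    attr(res, "consensus") <- paste(cons_b, collapse = "")
    res
}

#' Cluster repeat units into homologous regions
#'
#' Single-linkage clustering of units with inter-unit gap at most
#' \code{max_gap}; clusters with at least \code{min_units} type-A units become
#' hr regions.  When an annotation set is supplied, regions overlapping an ORF
#' by more than half the region length are dropped.  Each region reports its
#' AT content (N excluded).
#'
#' @param genome a \code{\link{circular_genome}}.
#' @param units data frame combining type-A and type-B units (columns
#'   \code{unit_type}, \code{start}, \code{end}, \code{orientation},
#'   \code{mismatches}).
#' @param min_units minimum number of type-A units per region (default 2).
#' @param max_gap maximum gap between consecutive units in a cluster
#'   (default 500 nt).
#' @param ann optional \code{\link{annotation_set}} used to drop ORF-embedded
#'   clusters.
#' @return a list of hr regions, each a list with \code{name}, \code{start},
#'   \code{end}, \code{units} (data frame), \code{at_percent}.
#' @export
call_hrs <- function(genome, units, min_units = 2L, max_gap = 500L, ann = NULL) {
    if (is.null(units) || nrow(units) == 0L) return(list())
    u <- units[order(units$start, units$end), , drop = FALSE]
    gap_prev <- c(0L, u$start[-1L] - cummax(u$end)[-nrow(u)] - 1L)
    grp <- cumsum(c(1L, as.integer(gap_prev[-1L] > max_gap)))
    regions <- list()
    for (g in split(seq_len(nrow(u)), grp)) {
        cl <- u[g, , drop = FALSE]
        if (sum(cl$unit_type == "A") < min_units) next
        start <- min(cl$start); end <- max(cl$end)
        if (!is.null(ann) && nrow(ann$orfs)) {
            ov <- pmin(ann$orfs$end, end) - pmax(ann$orfs$start, start) + 1L
            if (any(ov > (end - start + 1L) / 2)) next
        }
        slice <- .as_bases(substring(genome$sequence, start, end))
        acgt <- slice[slice != "N"]
        at <- if (length(acgt)) 100 * mean(acgt %in% c("A", "T")) else NA_real_
        regions[[length(regions) + 1L]] <-
            list(name = "", start = start, end = end,
                 units = `rownames<-`(cl, NULL), at_percent = at)
    }
    for (i in seq_along(regions)) regions[[i]]$name <- paste0("hr", i)
    regions
}

#' Compare the unit architecture of two hr sets
#'
#' Regions are paired by rank (hr1 with hr1, ...).  For each pair a minimal
#' edit script over the unit sequences is computed by token-level edit
#' distance (each unit is a token of type and orientation; only insertions
#' and deletions are allowed), and reported as runs with their nucleotide
#' extents.
#'
#' @param hrsA,hrsB hr region lists from \code{\link{call_hrs}}.
#' @return a list with one entry per rank-pair: \code{name_a}, \code{name_b},
#'   \code{edits} (data frame of op / which genome / token positions / unit
#'   count / nt extent); plus \code{unpaired} naming regions without a
#'   rank partner.
#' @export
diff_hr_architecture <- function(hrsA, hrsB) {
    n <- min(length(hrsA), length(hrsB))
    res <- list()
    for (i in seq_len(n)) {
        a <- hrsA[[i]]; b <- hrsB[[i]]
        ta <- paste(a$units$unit_type, a$units$orientation, sep = "/")
        tb <- paste(b$units$unit_type, b$units$orientation, sep = "/")
        res[[i]] <- list(name_a = a$name, name_b = b$name,
                         edits = .token_edit_script(ta, tb, a$units, b$units))
    }
    unpaired <- c(vapply(hrsA[seq_len(length(hrsA))[-seq_len(n)]], `[[`, "", "name"),
                  vapply(hrsB[seq_len(length(hrsB))[-seq_len(n)]], `[[`, "", "name"))
    list(pairs = res, unpaired = unpaired)
}

# minimal insert/delete edit script between token vectors (LCS-based),
# deterministic (prefer deletion on ties), reported as runs
.token_edit_script <- function(ta, tb, units_a, units_b) {
    n <- length(ta); m <- length(tb)
    D <- matrix(0L, n + 1L, m + 1L)
    D[, 1L] <- 0L:n; D[1L, ] <- 0L:m
    for (i in seq_len(n)) for (j in seq_len(m)) {
        D[i + 1L, j + 1L] <- if (ta[i] == tb[j]) D[i, j] else
            1L + min(D[i, j + 1L], D[i + 1L, j])
    }
    ops <- list()
    i <- n; j <- m
    while (i > 0L || j > 0L) {
        if (i > 0L && j > 0L && ta[i] == tb[j] && D[i + 1L, j + 1L] == D[i, j]) {
            i <- i - 1L; j <- j - 1L
        } else if (i > 0L && D[i + 1L, j + 1L] == D[i, j + 1L] + 1L) {
            ops[[length(ops) + 1L]] <- c(op = "delete", pos = i); i <- i - 1L
        } else {
            ops[[length(ops) + 1L]] <- c(op = "insert", pos = j); j <- j - 1L
        }
    }
    if (!length(ops)) {
        return(data.frame(op = character(), genome = character(), from_token = integer(),
                          to_token = integer(), n_units = integer(),
                          nt_start = integer(), nt_end = integer()))
    }
    om <- as.data.frame(do.call(rbind, rev(ops)))
    om$pos <- as.integer(om$pos)
    runs <- list()
    for (kind in c("delete", "insert")) {
        p <- sort(om$pos[om$op == kind])
        if (!length(p)) next
        grp <- cumsum(c(1L, as.integer(diff(p) > 1L)))
        for (g in split(p, grp)) {
            un <- if (kind == "delete") units_a[g, , drop = FALSE] else units_b[g, , drop = FALSE]
            runs[[length(runs) + 1L]] <- data.frame(
                op = kind, genome = if (kind == "delete") "A" else "B",
                from_token = min(g), to_token = max(g), n_units = length(g),
                nt_start = min(un$start), nt_end = max(un$end))
        }
    }
    out <- do.call(rbind, c(runs, make.row.names = FALSE))
    out[order(out$from_token, out$op), , drop = FALSE]
}
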