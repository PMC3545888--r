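.arm20 <- "GGCCAACCGGTTGGAACCGG"          # arbitrary 20-mer, no stray motifs
.pal40 <- paste0(.arm20, revcomp(.arm20)) # perfect 40-bp palindrome

test_that("palindrome scan finds constructed units and honours thresholds", {
    g <- circular_genome("t", paste0(strrep("C", 100), .pal40, strrep("G", 100)),
                         circular = FALSE)
    hit <- find_palindromes(g)
    expect_equal(nrow(hit), 1)
    expect_equal(hit$start, 101)
    expect_equal(hit$end, 140)
    expect_equal(hit$mismatches, 0)

    # two substitutions in one arm: found at tolerance >= 2, absent at <= 1
    v <- strsplit(.pal40, "")[[1]]
    v[3] <- "T"; v[7] <- "A"               # both were C
    pal_mut <- paste(v, collapse = "")
    g2 <- circular_genome("t", paste0(strrep("C", 100), pal_mut, strrep("G", 100)),
                          circular = FALSE)
    expect_equal(nrow(find_palindromes(g2, max_arm_mismatch = 2)), 1)
    expect_equal(find_palindromes(g2, max_arm_mismatch = 2)$mismatches, 4)
    expect_equal(nrow(find_palindromes(g2, max_arm_mismatch = 1)), 0)

    # longer than the genome: empty
    expect_equal(nrow(find_palindromes(circular_genome("t", "ACGTACGT"),
                                       unit_len = 40)), 0)
})

test_that("palindrome scan matches the exhaustive window oracle", {
    set.seed(31)
    for (rep in 1:40) {
        L <- sample(60:160, 1)
        circ <- rep %% 2 == 0
        s <- rand_dna(L, p = c(0.3, 0.2, 0.2, 0.3))
        got <- find_palindromes(as_genome(s, circular = circ),
                                unit_len = 10, max_arm_mismatch = 1)
        want <- oracle_palindromes(s, 10, 1, circular = circ)
        expect_equal(got$start, want$start, info = paste("rep", rep))
        expect_equal(got$mismatches, want$mismatches, info = paste("rep", rep))
    }
    # one 2-kb case at the full unit length
    s <- rand_dna(2000, p = c(0.35, 0.15, 0.15, 0.35))
    got <- find_palindromes(as_genome(s, FALSE), unit_len = 12, max_arm_mismatch = 2)
    want <- oracle_palindromes(s, 12, 2, circular = FALSE)
    expect_equal(got$start, want$start)
})

test_that("palindrome set is invariant under reverse complement", {
    set.seed(77)
    s <- rand_dna(800, p = c(0.3, 0.2, 0.2, 0.3))
    g <- as_genome(s, circular = FALSE)
    g_rc <- as_genome(revcomp(s), circular = FALSE)
    a <- find_palindromes(g, unit_len = 10, max_arm_mismatch = 1)
    b <- find_palindromes(g_rc, unit_len = 10, max_arm_mismatch = 1)
    # a type-A unit at [s, e] maps onto [L - e + 1, L - s + 1]; when a merge
    # cluster holds two equally good windows the reported representative may
    # sit anywhere within the cluster, so compare at cluster resolution
    expect_equal(nrow(a), nrow(b))
    mapped <- sort(800 - b$end + 1)
    expect_true(all(abs(mapped - sort(a$start)) <= 5))
    expect_equal(sort(b$mismatches), sort(a$mismatches))
})

test_that("flank repeats are recovered from a planted B-A-B cassette", {
    b31 <- "GGCCAAGGTTCCAAGGCCTTGGAACCGGTTC"
    expect_equal(nchar(b31), 31)
    set.seed(301)
    seq <- paste0(rand_dna(120), b31, "GCGCG", .pal40, "CGCGC", b31, rand_dna(120))
    g <- circular_genome("t", seq, circular = FALSE)
    pals <- find_palindromes(g)
    expect_equal(nrow(pals), 1)
    fl <- find_flank_repeats(g, pals)
    expect_equal(nrow(fl), 2)
    expect_setequal(fl$side, c("left", "right"))
    expect_equal(sort(fl$start), c(121, 121 + 31 + 5 + 40 + 5))
    expect_equal(fl$mismatches, c(0, 0))

    # palindrome alone: no B units at all
    set.seed(302)
    g2 <- circular_genome("t", paste0(rand_dna(120), .pal40, rand_dna(120)),
                          circular = FALSE)
    pal2 <- find_palindromes(g2)
    expect_equal(nrow(find_flank_repeats(g2, pal2)), 0)
})

test_that("flank repeats beyond the mismatch tolerance are rejected", {
    b31 <- "GGCCAAGGTTCCAAGGCCTTGGAACCGGTTC"
    v <- strsplit(b31, "")[[1]]
    stopifnot(v[c(2, 8, 14, 26, 29)] != c("T", "T", "T", "T", "A"))
    v[c(2, 8, 14, 26, 29)] <- c("T", "T", "T", "T", "A")   # 5 real mismatches
    b_bad <- paste(v, collapse = "")
    set.seed(303)
    cassette <- function() paste0(b31, "GCGCG", .pal40, "CGCGC", b_bad)
    seq <- paste0(rand_dna(120), cassette(), rand_dna(700), cassette(),
                  rand_dna(120))
    g <- circular_genome("t", seq, circular = FALSE)
    pals <- find_palindromes(g)
    expect_equal(nrow(pals), 2)
    fl <- find_flank_repeats(g, pals, max_mismatch = 4)
    expect_equal(nrow(fl), 2)                 # the two perfect left flanks only
    expect_equal(unique(fl$side), "left")
    expect_equal(fl$mismatches, c(0, 0))
})

test_that("hr calling clusters planted cassettes at their true spans", {
    cfg <- generator_config(seed = 13, n_orfs = 12, n_hr_cassettes = 4)
    gt <- generate_annotated_genome(cfg)
    g <- gt$genome
    pals <- find_palindromes(g)
    fl <- find_flank_repeats(g, pals)
    units <- rbind(pals[c("unit_type", "start", "end", "orientation", "mismatches")],
                   fl[c("unit_type", "start", "end", "orientation", "mismatches")])
    hrs <- call_hrs(g, units)
    expect_length(hrs, nrow(gt$truth$hr_regions))
    for (i in seq_along(hrs)) {
        expect_lte(abs(hrs[[i]]$start - gt$truth$hr_regions$start[i]), 55)
        expect_lte(abs(hrs[[i]]$end - gt$truth$hr_regions$end[i]), 55)
        expect_gte(hrs[[i]]$at_percent, 50)
    }
    # region span equals the outermost unit boundaries
    for (h in hrs) {
        expect_equal(h$start, min(h$units$start))
        expect_equal(h$end, max(h$units$end))
    }
})

test_that("scattered single units do not become regions", {
    units <- data.frame(unit_type = "A", start = c(100, 2000, 5000),
                        end = c(139, 2039, 5039), orientation = "forward",
                        mismatches = 0)
    g <- circular_genome("t", rand_dna(6000), circular = FALSE)
    expect_length(call_hrs(g, units, min_units = 2, max_gap = 500), 0)
})

test_that("hr fixture interval arithmetic reproduces the published sizes", {
    ann <- hearmnpv_annotation()
    len <- ann$hrs$end - ann$hrs$start + 1
    expect_equal(len, c(1185, 1766, 1074, 724))
    expect_equal(sum(len), 4749)
    expect_equal(round(100 * sum(len) / ann$genome_length, 2), 3.08)
})

test_that("architecture diff reports identity, single edits, and planted runs", {
    mk_units <- function(types, start0 = 100) {
        n <- length(types)
        starts <- start0 + (seq_len(n) - 1) * 50
        data.frame(unit_type = types, start = starts,
                   end = starts + ifelse(types == "A", 39, 30),
                   orientation = "forward", mismatches = 0)
    }
    reg <- function(u, name) list(name = name, start = min(u$start),
                                  end = max(u$end), units = u, at_percent = 60)
    a <- reg(mk_units(c("B", "A", "B", "A", "B")), "hr1")
    # identical: empty edit script
    d <- diff_hr_architecture(list(a), list(a))
    expect_equal(nrow(d$pairs[[1]]$edits), 0)
    # one extra A token in B: a single one-unit insertion
    b <- reg(mk_units(c("B", "A", "B", "A", "A", "B")), "hr1")
    d <- diff_hr_architecture(list(a), list(b))
    e <- d$pairs[[1]]$edits
    expect_equal(nrow(e), 1)
    expect_equal(e$op, "insert")
    expect_equal(e$n_units, 1)
    # planted 2-token deletion is recovered exactly
    c2 <- reg(mk_units(c("B", "A", "B")), "hr1")
    d <- diff_hr_architecture(list(a), list(c2))
    e <- d$pairs[[1]]$edits
    expect_equal(nrow(e), 1)
    expect_equal(e$op, "delete")
    expect_equal(e$n_units, 2)
    # unequal list lengths: unpaired regions reported
    d <- diff_hr_architecture(list(a, b), list(a))
    expect_equal(d$unpaired, "hr1")
})
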