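# Containers and I/O for circular genomes and the ORF-table annotation dialect.
#
# Coordinate convention used by the whole package: 1-based inclusive, with
# position 1 the adenine of the polyhedrin start codon (the conventional zero
# point of an NPV physical map).  Features that wrap the origin of a circular
# genome are stored with start > end plus a wrap flag; their nucleotide span is
# end - start + 1 + genome_length.

#' Construct a circular genome
#'
#' A minimal container for a circular (or linear) nucleotide sequence with
#' 1-based coordinates.
#'
#' @param id record identifier.
#' @param sequence nucleotide string; lower case is folded to upper case.
#'   Only A, C, G, T, N are accepted.  N is tolerated (draft-genome support)
#'   but excluded from base-composition statistics.
#' @param circular logical; is the molecule circular?
#' @return an object of class \code{circular_genome} with fields \code{id},
#'   \code{sequence}, \code{length}, \code{circular}.
#' @export
circular_genome <- function(id, sequence, circular = TRUE) {
    stopifnot(is.character(id), length(id) == 1L, nzchar(id),
              is.character(sequence), length(sequence) == 1L,
              is.logical(circular), length(circular) == 1L)
    sequence <- toupper(sequence)
    bad <- gsub("[ACGTN]", "", sequence)
    if (nzchar(bad)) {
        stop("sequence of record '", id, "' contains non-nucleotide characters: ",
             paste(unique(.as_bases(bad)), collapse = ", "))
    }
    structure(list(id = id, sequence = sequence,
                   length = nchar(sequence), circular = circular),
              class = "circular_genome")
}

#' @export
print.circular_genome <- function(x, ...) {
    cat(sprintf("<circular_genome> %s: %s bp (%s)\n", x$id,
                format(x$length, big.mark = ","),
                if (x$circular) "circular" else "linear"))
    invisible(x)
}

#' Read genomes from a FASTA file
#'
#' @param path FASTA file (one or more records).
#' @param circular logical flag applied to every record (default TRUE).
#' @return a list of \code{\link{circular_genome}}, in file order.
#' @export
read_fasta <- function(path, circular = TRUE) {
    if (!file.exists(path)) stop("file not found: ", path)
    set <- Biostrings::readBStringSet(path)
    if (length(set) == 0L) stop("FASTA file '", path, "' contains no records")
    ids <- sub("\\s.*$", "", names(set))
    dup <- ids[duplicated(ids)]
    if (length(dup)) stop("duplicate FASTA ids: ", paste(unique(dup), collapse = ", "))
    lapply(seq_along(set), function(i) {
        circular_genome(ids[i], as.character(set[[i]]), circular = circular)
    })
}

#' Write genomes to a FASTA file
#'
#' @param genomes a \code{circular_genome} or list of them.
#' @param path output path.
#' @param width line width for wrapping.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(genomes, path, width = 70L) {
    if (inherits(genomes, "circular_genome")) genomes <- list(genomes)
    con <- file(path, "w")
    on.exit(close(con))
    for (g in genomes) {
        writeLines(paste0(">", g$id), con)
        starts <- seq(1L, g$length, by = width)
        writeLines(substring(g$sequence, starts, pmin(starts + width - 1L, g$length)), con)
    }
    invisible(path)
}

#' Nucleotide span of a (possibly origin-wrapping) inclusive interval
#'
#' @param start,end 1-based inclusive endpoints.
#' @param wrap logical; does the feature cross the origin?
#' @param genome_length needed for wrapping features.
#' @return span in nucleotides: end - start + 1 (+ genome length if wrapped).
#' @export
orf_span_nt <- function(start, end, wrap = start > end, genome_length = NA_integer_) {
    ifelse(wrap, end - start + 1L + genome_length, end - start + 1L)
}

#' Construct an annotation set
#'
#' Bundles the ORF table, per-virus homolog identities, and hr intervals of
#' one genome.
#'
#' @param genome_id genome identifier.
#' @param genome_length genome length in nucleotides.
#' @param orfs data frame with columns \code{index}, \code{name}, \code{start},
#'   \code{end}, \code{strand} ("+"/"-"), \code{length_aa},
#'   \code{promoter_class} (early/late/both/none/unassigned) and optionally
#'   \code{wrap}; rows are sorted by \code{start} and re-checked for contiguous
#'   indices from 1.
#' @param homologs optional long-format data frame with columns
#'   \code{orf_index}, \code{virus}, \code{homolog_orf}, \code{pct_identity}.
#' @param hrs optional data frame with columns \code{name}, \code{start},
#'   \code{end} giving homologous-region intervals.  hr intervals may not
#'   overlap any ORF span.
#' @param viruses character vector fixing the homolog column order on export.
#' @return an object of class \code{annotation_set}.
#' @export
annotation_set <- function(genome_id, genome_length, orfs,
                           homologs = NULL, hrs = NULL, viruses = NULL) {
    stopifnot(is.character(genome_id), length(genome_id) == 1L,
              is.numeric(genome_length), genome_length >= 1)
    genome_length <- as.integer(genome_length)
    orfs <- as.data.frame(orfs)
    if (!"name" %in% names(orfs)) orfs$name <- ""
    if (!"promoter_class" %in% names(orfs)) orfs$promoter_class <- "unassigned"
    need <- c("index", "start", "end", "strand", "length_aa")
    miss <- setdiff(need, names(orfs))
    if (length(miss)) stop("orfs is missing columns: ", paste(miss, collapse = ", "))
    if (!"wrap" %in% names(orfs)) orfs$wrap <- orfs$start > orfs$end
    if (nrow(orfs)) {
        if (any(orfs$start < 1 | orfs$start > genome_length |
                orfs$end < 1 | orfs$end > genome_length)) {
            stop("ORF coordinates outside [1, ", genome_length, "]")
        }
        if (!all(orfs$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
        orfs <- orfs[order(orfs$start), , drop = FALSE]
        orfs$index <- seq_len(nrow(orfs))
        rownames(orfs) <- NULL
    }
    if (is.null(homologs)) {
        homologs <- data.frame(orf_index = integer(), virus = character(),
                               homolog_orf = character(), pct_identity = numeric())
    }
    if (is.null(hrs)) {
        hrs <- data.frame(name = character(), start = integer(), end = integer())
    }
    hrs <- as.data.frame(hrs)
    if (nrow(hrs) && nrow(orfs)) {
        for (i in seq_len(nrow(hrs))) {
            ov <- pmin(orfs$end, hrs$end[i]) - pmax(orfs$start, hrs$start[i]) + 1L
            if (any(ov > 0 & !orfs$wrap)) {
                stop("hr interval '", hrs$name[i], "' overlaps an ORF span")
            }
        }
    }
    if (is.null(viruses)) viruses <- unique(homologs$virus)
    structure(list(genome_id = genome_id, genome_length = genome_length,
                   orfs = orfs, homologs = as.data.frame(homologs),
                   hrs = hrs, viruses = viruses),
              class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
    cat(sprintf("<annotation_set> %s (%s bp): %d ORFs, %d hrs, %d homolog entries\n",
                x$genome_id, format(x$genome_length, big.mark = ","),
                nrow(x$orfs), nrow(x$hrs), nrow(x$homologs)))
    invisible(x)
}

.prm_to_class <- function(x) {
    x <- trimws(x)
    out <- rep("none", length(x))
    out[x == "E"] <- "early"
    out[x == "L"] <- "late"
    out[x %in% c("E,L", "L,E")] <- "both"
    out
}

.class_to_prm <- function(x) {
    c(early = "E", late = "L", both = "E,L", none = "", unassigned = "")[x]
}

#' Read an ORF annotation table
#'
#' Parses the tab-separated annotation dialect: columns \code{ORF},
#' \code{Name}, \code{Start}, \code{Orient} (literal ">"/"<"), \code{End},
#' \code{Prm} (E / L / "E,L" / blank), \code{Length_aa}, then repeated
#' \code{<Virus>_ORF} / \code{<Virus>_Pctid} column pairs, one per comparison
#' virus.  Rows with an empty ORF index whose name matches \code{hr*} are hr
#' intervals (Name/Start/End only).
#'
#' A row whose genomic span differs from 3*length_aa + 3 is kept but flagged
#' (column \code{span_flag}) with a warning.
#'
#' @param path the TSV file.
#' @param genome_id identifier recorded in the result.
#' @param genome_length genome length; when NA the maximum coordinate seen is
#'   used and range validation is skipped.
#' @return an \code{\link{annotation_set}}.
#' @export
read_annotation_table <- function(path, genome_id = "genome", genome_length = NA) {
    if (!file.exists(path)) stop("file not found: ", path)
    tab <- read.delim(path, colClasses = "character", check.names = FALSE)
    if (nrow(tab) == 0L) stop("no records in annotation table '", path, "'")
    is_hr <- !nzchar(trimws(tab$ORF)) & grepl("^hr", trimws(tab$Name))
    hrs <- data.frame(name = trimws(tab$Name[is_hr]),
                      start = as.integer(tab$Start[is_hr]),
                      end = as.integer(tab$End[is_hr]))
    body <- tab[!is_hr, , drop = FALSE]
    if (nrow(body) == 0L) stop("no ORF records in annotation table '", path, "'")
    orfs <- data.frame(index = as.integer(body$ORF),
                       name = trimws(body$Name),
                       start = as.integer(body$Start),
                       end = as.integer(body$End),
                       strand = ifelse(trimws(body$Orient) == "<", "-", "+"),
                       length_aa = as.integer(body$Length_aa),
                       promoter_class = .prm_to_class(body$Prm))
    if (is.na(genome_length)) genome_length <- max(orfs$end, orfs$start, hrs$end, 1L)
    orfs$wrap <- orfs$start > orfs$end
    span <- orf_span_nt(orfs$start, orfs$end, orfs$wrap, genome_length)
    orfs$span_flag <- span != 3L * orfs$length_aa + 3L
    if (any(orfs$span_flag)) {
        warning(sum(orfs$span_flag),
                " ORF row(s) with span inconsistent with 3*aa+3 (kept, flagged): ",
                paste(head(orfs$index[orfs$span_flag], 5L), collapse = ", "))
    }
    virus_cols <- grep("_ORF$", names(tab), value = TRUE)
    viruses <- sub("_ORF$", "", virus_cols)
    hom <- list()
    for (v in viruses) {
        id <- trimws(body[[paste0(v, "_ORF")]])
        pc <- trimws(body[[paste0(v, "_Pctid")]])
        keep <- nzchar(id) | nzchar(pc)
        if (any(keep)) {
            hom[[v]] <- data.frame(orf_index = orfs$index[keep], virus = v,
                                   homolog_orf = id[keep],
                                   pct_identity = as.numeric(pc[keep]))
        }
    }
    homologs <- if (length(hom)) do.call(rbind, c(hom, make.row.names = FALSE)) else NULL
    annotation_set(genome_id, genome_length, orfs, homologs, hrs, viruses = viruses)
}

#' Write an annotation set in the ORF-table dialect
#'
#' Inverse of \code{\link{read_annotation_table}}; a read-write-read cycle is
#' lossless for all fields except that an \code{unassigned} promoter class is
#' written as a blank cell (the dialect has no spelling for it) and reads back
#' as \code{none}.
#'
#' @param ann an \code{\link{annotation_set}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_annotation_table <- function(ann, path) {
    stopifnot(inherits(ann, "annotation_set"))
    orfs <- ann$orfs
    out <- data.frame(ORF = orfs$index, Name = orfs$name, Start = orfs$start,
                      Orient = ifelse(orfs$strand == "-", "<", ">"),
                      End = orfs$end, Prm = unname(.class_to_prm(orfs$promoter_class)),
                      Length_aa = orfs$length_aa, check.names = FALSE)
    for (v in ann$viruses) {
        hv <- ann$homologs[ann$homologs$virus == v, , drop = FALSE]
        idc <- rep("", nrow(orfs)); pcc <- rep("", nrow(orfs))
        m <- match(orfs$index, hv$orf_index)
        idc[!is.na(m)] <- hv$homolog_orf[m[!is.na(m)]]
        pcc[!is.na(m)] <- format(hv$pct_identity[m[!is.na(m)]], trim = TRUE)
        out[[paste0(v, "_ORF")]] <- idc
        out[[paste0(v, "_Pctid")]] <- pcc
    }
    if (nrow(ann$hrs)) {
        for (i in seq_len(nrow(ann$hrs))) {
            row <- as.list(rep("", ncol(out)))
            names(row) <- names(out)
            row$Name <- ann$hrs$name[i]
            row$Start <- ann$hrs$start[i]
            row$End <- ann$hrs$end[i]
            out <- rbind(out, as.data.frame(row, check.names = FALSE))
        }
    }
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Load the packaged HearMNPV ORF table
#'
#' The packaged fixture is a faithful transcription of the published HearMNPV
#' annotation table: 162 ORFs, four hr intervals, and per-virus homolog
#' identity columns for six comparison viruses.  The genome is 154,196 bp.
#'
#' @return an \code{\link{annotation_set}}.
#' @export
hearmnpv_annotation <- function() {
    path <- system.file("extdata", "hearmnpv_table1.tsv", package = "baculann",
                        mustWork = TRUE)
    read_annotation_table(path, genome_id = "HearMNPV", genome_length = 154196L)
}

#' Export an annotation set as GFF3
#'
#' ORFs become \code{CDS} features and hrs \code{repeat_region} features,
#' 1-based inclusive.  An origin-wrapping feature is emitted as two part lines
#' sharing an \code{ID} attribute.
#'
#' @param ann an \code{\link{annotation_set}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_gff3 <- function(ann, path) {
    stopifnot(inherits(ann, "annotation_set"))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("##gff-version 3", con)
    writeLines(sprintf("##sequence-region %s 1 %d", ann$genome_id, ann$genome_length), con)
    fmt <- function(start, end, type, strand, attrs) {
        sprintf("%s\tbaculann\t%s\t%d\t%d\t.\t%s\t%s\t%s",
                ann$genome_id, type, start, end, strand,
                if (type == "CDS") "0" else ".", attrs)
    }
    for (i in seq_len(nrow(ann$orfs))) {
        o <- ann$orfs[i, ]
        attrs <- sprintf("ID=orf%d;promoter_class=%s", o$index, o$promoter_class)
        if (nzchar(o$name)) attrs <- paste0(attrs, ";Name=", o$name)
        if (isTRUE(o$wrap)) {
            writeLines(fmt(o$start, ann$genome_length, "CDS", o$strand,
                           paste0(attrs, ";part=1")), con)
            writeLines(fmt(1L, o$end, "CDS", o$strand, paste0(attrs, ";part=2")), con)
        } else {
            writeLines(fmt(o$start, o$end, "CDS", o$strand, attrs), con)
        }
    }
    for (i in seq_len(nrow(ann$hrs))) {
        h <- ann$hrs[i, ]
        writeLines(fmt(h$start, h$end, "repeat_region", ".",
                       sprintf("ID=%s;Name=%s", h$name, h$name)), con)
    }
    invisible(path)
}

#' Minimal GFF3 reader for files produced by \code{\link{write_gff3}}
#'
#' Reads CDS and repeat_region features; CDS part lines sharing an ID are
#' re-joined into one origin-wrapping record.
#'
#' @param path GFF3 file.
#' @param genome_length optional; taken from the sequence-region pragma when
#'   present.
#' @return an \code{\link{annotation_set}} (promoter classes and names are
#'   recovered from the attribute column; homolog columns are not part of GFF3).
#' @export
read_gff3 <- function(path, genome_length = NA) {
    lines <- readLines(path)
    sr <- grep("^##sequence-region", lines, value = TRUE)
    genome_id <- "genome"
    if (length(sr)) {
        f <- strsplit(sr[1L], "\\s+")[[1L]]
        genome_id <- f[2L]
        if (is.na(genome_length)) genome_length <- as.integer(f[4L])
    }
    lines <- lines[!grepl("^#", lines) & nzchar(lines)]
    if (!length(lines)) stop("no features in '", path, "'")
    f <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
    attr_get <- function(s, key) {
        m <- regmatches(s, regexec(paste0("(?:^|;)", key, "=([^;]*)"), s))
        vapply(m, function(x) if (length(x) == 2L) x[2L] else "", "")
    }
    type <- f[, 3L]
    df <- data.frame(type = type, start = as.integer(f[, 4L]), end = as.integer(f[, 5L]),
                     strand = f[, 7L], id = attr_get(f[, 9L], "ID"),
                     name = attr_get(f[, 9L], "Name"),
                     pclass = attr_get(f[, 9L], "promoter_class"),
                     part = attr_get(f[, 9L], "part"))
    cds <- df[df$type == "CDS", , drop = FALSE]
    orfs_list <- lapply(split(cds, cds$id), function(g) {
        if (nrow(g) == 2L) {  # origin-wrapping pair of part lines
            g <- g[order(g$part), ]
            start <- g$start[1L]; end <- g$end[2L]; wrap <- TRUE
        } else {
            start <- g$start; end <- g$end; wrap <- FALSE
        }
        span <- orf_span_nt(start, end, wrap, genome_length)
        data.frame(index = 0L, name = g$name[1L], start = start, end = end,
                   strand = g$strand[1L], length_aa = (span - 3L) %/% 3L,
                   promoter_class = if (nzchar(g$pclass[1L])) g$pclass[1L] else "unassigned",
                   wrap = wrap)
    })
    orfs <- do.call(rbind, c(orfs_list, make.row.names = FALSE))
    hr <- df[df$type == "repeat_region", , drop = FALSE]
    hrs <- if (nrow(hr)) data.frame(name = hr$name, start = hr$start, end = hr$end) else NULL
    annotation_set(genome_id, genome_length, orfs, hrs = hrs)
}
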