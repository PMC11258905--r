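#' Read gene features from a GFF3 file
#'
#' Parses gene/exon/CDS/UTR records into a feature table. File coordinates
#' (1-based inclusive) are converted to the package's internal 0-based
#' half-open convention. Feature kinds outside the supported set are skipped
#' and the number skipped is reported with a message. Children are resolved
#' to their gene via `Parent=` attributes (through mRNA records if present).
#'
#' @param path Path to a GFF3 file.
#' @return A tibble with columns `chrom`, `start`, `end` (0-based half-open),
#'   `strand`, `kind`, `gene_id`.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), strand = character(),
                          kind = character(), gene_id = character()))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  ncol_ok <- lengths(f) >= 9
  if (any(!ncol_ok))
    stop("GFF3 line ", lineno[!ncol_ok][1], ": fewer than 9 columns",
         call. = FALSE)
  m <- do.call(rbind, f)
  start1 <- suppressWarnings(as.integer(m[, 4]))
  end1 <- suppressWarnings(as.integer(m[, 5]))
  if (anyNA(start1) || anyNA(end1))
    stop("GFF3 line ", lineno[which(is.na(start1) | is.na(end1))[1]],
         ": non-integer coordinate", call. = FALSE)
  bad <- end1 < start1
  if (any(bad))
    stop("GFF3 line ", lineno[bad][1], ": end < start", call. = FALSE)

  kinds <- c("gene", "exon", "CDS", "five_prime_UTR", "three_prime_UTR")
  type <- m[, 3]
  attrs <- m[, 9]
  get_attr <- function(a, key) {
    v <- stringr::str_match(a, paste0("(?:^|;)", key, "=([^;]+)"))[, 2]
    v
  }
  id <- get_attr(attrs, "ID")
  parent <- get_attr(attrs, "Parent")

  # resolve transcript-level parents (mRNA etc.) to their gene
  tx <- !(type %in% c("gene")) & !(type %in% kinds)
  tx_map <- stats::setNames(parent[tx], id[tx])
  gene_of <- function(p) {
    hop <- tx_map[p]
    ifelse(!is.na(hop), hop, p)
  }
  gene_id <- ifelse(type == "gene", id, gene_of(parent))

  supported <- type %in% kinds
  n_skip <- sum(!supported & type != "mRNA")
  if (n_skip > 0)
    message("read_gff3: skipped ", n_skip, " record(s) of unsupported kind")

  out <- tibble::tibble(
    chrom = m[supported, 1],
    start = start1[supported] - 1L,
    end = end1[supported],
    strand = ifelse(m[supported, 7] %in% c("+", "-"), m[supported, 7], "."),
    kind = type[supported],
    gene_id = gene_id[supported]
  )
  dplyr::arrange(out, .data$chrom, .data$start, .data$end)
}

#' Write a feature table to GFF3
#'
#' @param features Feature tibble as returned by [read_gff3()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path) {
  hdr <- "##gff-version 3"
  body <- sprintf("%s\tsexmarkr\t%s\t%d\t%d\t.\t%s\t.\t%s",
                  features$chrom, features$kind,
                  features$start + 1L, features$end,
                  features$strand,
                  ifelse(features$kind == "gene",
                         paste0("ID=", features$gene_id),
                         paste0("Parent=", features$gene_id)))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read alignment blocks from a PAF file
#'
#' @param path Path to a PAF file (12 or more tab-separated columns).
#' @return A tibble of alignment blocks with columns `qname`, `qlen`,
#'   `qstart`, `qend`, `strand`, `tname`, `tlen`, `tstart`, `tend`,
#'   `matches`, `block_len`. PAF coordinates are already 0-based half-open.
#' @export
read_paf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  empty <- tibble::tibble(
    qname = character(), qlen = integer(), qstart = integer(),
    qend = integer(), strand = character(), tname = character(),
    tlen = integer(), tstart = integer(), tend = integer(),
    matches = integer(), block_len = integer()
  )
  if (length(lines) == 0) return(empty)
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 12))
    stop("PAF line ", which(lengths(f) < 12)[1], ": fewer than 12 columns",
         call. = FALSE)
  m <- t(vapply(f, function(x) x[1:12], character(12)))
  ints <- function(j) {
    v <- suppressWarnings(as.integer(m[, j]))
    if (anyNA(v))
      stop("PAF line ", which(is.na(v))[1], ": non-integer coordinate",
           call. = FALSE)
    v
  }
  tibble::tibble(
    qname = m[, 1], qlen = ints(2), qstart = ints(3), qend = ints(4),
    strand = m[, 5], tname = m[, 6], tlen = ints(7), tstart = ints(8),
    tend = ints(9), matches = ints(10), block_len = ints(11)
  )
}

#' Write alignment blocks to a PAF file
#'
#' @param blocks Alignment-block tibble (see [read_paf()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_paf <- function(blocks, path) {
  mapq <- col_or(blocks, "mapq", rep(60L, nrow(blocks)))
  writeLines(sprintf("%s\t%d\t%d\t%d\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t%d",
                     blocks$qname, blocks$qlen, blocks$qstart, blocks$qend,
                     blocks$strand, blocks$tname, blocks$tlen, blocks$tstart,
                     blocks$tend, blocks$matches, blocks$block_len, mapq),
             path)
  invisible(path)
}

catalog_tsv_cols <- c("id", "type", "ref_chrom", "ref_start_1based",
                      "ref_end_1based", "length", "region_class", "sequence",
                      "source", "ref_label", "qry_chrom", "qry_start_1based",
                      "qry_end_1based", "flags")

# render internal 0-based half-open variant coordinates as 1-based inclusive.
# INS breakpoints (zero-width) render as [pos, pos+1] where pos is the 1-based
# position of the base AFTER which the insertion sits ("after TTTAGC" style).
variant_to_1based <- function(type, start0, end0) {
  ins <- rep_len(type == "INS", length(start0))
  tibble::tibble(start1 = ifelse(ins, start0, start0 + 1L),
                 end1 = ifelse(ins, start0 + 1L, end0))
}

variant_from_1based <- function(type, start1, end1) {
  ins <- rep_len(type == "INS", length(start1))
  tibble::tibble(start0 = ifelse(ins, start1, start1 - 1L),
                 end0 = ifelse(ins, start1, end1))
}

#' Write a variant catalog to TSV or VCF
#'
#' The TSV layout opens with the fixed columns `id`, `type`, `ref_chrom`,
#' `ref_start_1based`, `ref_end_1based`, `length`, `region_class`,
#' `sequence`, `source`, followed by query-side columns that make the file a
#' lossless round trip with [read_variant_catalog()]. The VCF rendering uses
#' 1-based `POS` with the anchored-base indel convention (`REF` holds the
#' base before the event) and `INFO` keys `SVTYPE`, `SVLEN` and `END`.
#'
#' @param variants Variant catalog tibble (see [call_variants()]).
#' @param path Output path.
#' @param format `"tsv"` or `"vcf"`.
#' @param genome Reference [genome], used by the VCF writer to fetch anchor
#'   bases; when absent the anchor is written as `N`.
#' @return `path`, invisibly.
#' @export
write_variant_catalog <- function(variants, path, format = c("tsv", "vcf"),
                                  genome = NULL) {
  format <- match.arg(format)
  if (nrow(variants) > 0 && length(unique(variants$ref_label)) > 1)
    stop("catalog mixes reference labels: ",
         paste(unique(variants$ref_label), collapse = ", "), call. = FALSE)
  if (format == "tsv") {
    co <- variant_to_1based(variants$type, variants$ref_start, variants$ref_end)
    cq <- variant_from_to_q1(variants)
    out <- tibble::tibble(
      id = variants$id, type = variants$type,
      ref_chrom = variants$ref_chrom,
      ref_start_1based = co$start1, ref_end_1based = co$end1,
      length = variants$length,
      region_class = col_or(variants, "region_class",
                            rep(NA_character_, nrow(variants))),
      sequence = variants$sequence, source = variants$source,
      ref_label = variants$ref_label, qry_chrom = variants$qry_chrom,
      qry_start_1based = cq$start1, qry_end_1based = cq$end1,
      flags = col_or(variants, "flags", rep("", nrow(variants)))
    )
    readr::write_tsv(out, path, na = "")
  } else {
    anchor <- function(chrom, pos0) {
      if (is.null(genome)) return(rep("N", length(chrom)))
      mapply(function(ch, p) {
        if (p < 1) "N" else genome_subseq(genome, ch, p - 1, p)
      }, chrom, pos0, USE.NAMES = FALSE)
    }
    hdr <- c(
      "##fileformat=VCFv4.2",
      "##source=sexmarkr",
      "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Variant type\">",
      "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Signed variant length\">",
      "##INFO=<ID=END,Number=1,Type=Integer,Description=\"1-based end on reference\">",
      "##INFO=<ID=QPOS,Number=1,Type=String,Description=\"Query chrom:start-end (1-based)\">",
      "##INFO=<ID=SRC,Number=1,Type=String,Description=\"Calling source\">",
      "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
    )
    if (nrow(variants) == 0) { writeLines(hdr, path); return(invisible(path)) }
    v <- variants
    a <- anchor(v$ref_chrom, v$ref_start)
    pos <- v$ref_start  # 1-based position of the anchor base
    ref <- ifelse(v$type == "DEL" | v$type == "SUB",
                  paste0(a, v$sequence), a)
    alt <- ifelse(v$type == "INS", paste0(a, v$sequence), a)
    svlen <- ifelse(v$type == "DEL", -v$length, v$length)
    cq <- variant_from_to_q1(v)
    info <- sprintf("SVTYPE=%s;SVLEN=%d;END=%d;QPOS=%s:%d-%d;SRC=%s",
                    v$type, svlen, pmax(v$ref_end, v$ref_start), v$qry_chrom,
                    cq$start1, cq$end1, v$source)
    body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t%s",
                    v$ref_chrom, pos, v$id, ref, alt, info)
    writeLines(c(hdr, body), path)
  }
  invisible(path)
}

variant_from_to_q1 <- function(v) {
  # query-side 1-based rendering: DEL has a zero-width query breakpoint
  del <- v$type == "DEL"
  tibble::tibble(start1 = ifelse(del, v$qry_start, v$qry_start + 1L),
                 end1 = ifelse(del, v$qry_start + 1L, v$qry_end))
}

#' Read a variant catalog written by [write_variant_catalog()]
#'
#' @param path Path to a catalog TSV or VCF.
#' @param format `"tsv"` or `"vcf"`.
#' @return A variant catalog tibble with internal 0-based half-open
#'   coordinates.
#' @export
read_variant_catalog <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "tsv") {
    x <- readr::read_tsv(path, col_types = readr::cols(
      id = "c", type = "c", ref_chrom = "c", ref_start_1based = "i",
      ref_end_1based = "i", length = "i", region_class = "c", sequence = "c",
      source = "c", ref_label = "c", qry_chrom = "c", qry_start_1based = "i",
      qry_end_1based = "i", flags = "c"
    ))
    co <- variant_from_1based(x$type, x$ref_start_1based, x$ref_end_1based)
    del <- x$type == "DEL"
    tibble::tibble(
      id = x$id, type = x$type, ref_label = x$ref_label,
      ref_chrom = x$ref_chrom, ref_start = co$start0, ref_end = co$end0,
      qry_chrom = x$qry_chrom,
      qry_start = ifelse(del, x$qry_start_1based, x$qry_start_1based - 1L),
      qry_end = ifelse(del, x$qry_start_1based, x$qry_end_1based),
      length = x$length,
      sequence = ifelse(is.na(x$sequence), "", x$sequence),
      source = x$source,
      flags = ifelse(is.na(x$flags), "", x$flags)
    )
  } else {
    lines <- readLines(path)
    body <- lines[!grepl("^#", lines) & nzchar(lines)]
    if (length(body) == 0) return(empty_catalog())
    f <- strsplit(body, "\t", fixed = TRUE)
    m <- do.call(rbind, f)
    info_get <- function(info, key) {
      stringr::str_match(info, paste0("(?:^|;)", key, "=([^;]+)"))[, 2]
    }
    info <- m[, 8]
    type <- info_get(info, "SVTYPE")
    qpos <- stringr::str_match(info_get(info, "QPOS"),
                               "^(.*):(\\d+)-(\\d+)$")
    pos <- as.integer(m[, 2])
    ref <- m[, 4]; alt <- m[, 5]
    seqs <- ifelse(type == "INS", substr(alt, 2, nchar(alt)),
                   substr(ref, 2, nchar(ref)))
    len <- abs(as.integer(info_get(info, "SVLEN")))
    q1 <- as.integer(qpos[, 3]); q2 <- as.integer(qpos[, 4])
    del <- type == "DEL"
    tibble::tibble(
      id = m[, 3], type = type, ref_label = NA_character_,
      ref_chrom = m[, 1],
      ref_start = pos,
      ref_end = ifelse(type == "INS", pos, pos + len),
      qry_chrom = qpos[, 2],
      qry_start = ifelse(del, q1, q1 - 1L),
      qry_end = ifelse(del, q1, q2),
      length = len, sequence = seqs,
      source = info_get(info, "SRC"),
      flags = ""
    )
  }
}

empty_catalog <- function(ref_label = NA_character_) {
  tibble::tibble(
    id = character(), type = character(), ref_label = character(),
    ref_chrom = character(), ref_start = integer(), ref_end = integer(),
    qry_chrom = character(), qry_start = integer(), qry_end = integer(),
    length = integer(), sequence = character(), source = character(),
    flags = character()
  )
}

#' Read a per-base depth track
#'
#' The track is a TSV with columns `chrom`, `pos_1based`, `depth` (any
#' external tool, e.g. `samtools depth`, can produce it). Positions are
#' converted to 0-based.
#'
#' @param path Path to a depth TSV.
#' @return A tibble with columns `chrom`, `pos` (0-based), `depth`.
#' @export
read_depth_track <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    chrom = "c", pos_1based = "i", depth = "d"))
  if (any(x$depth < 0)) stop("negative depth in ", path, call. = FALSE)
  tibble::tibble(chrom = x$chrom, pos = x$pos_1based - 1L, depth = x$depth)
}

#' Write a per-base depth track
#'
#' @param track Depth tibble with columns `chrom`, `pos` (0-based), `depth`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_depth_track <- function(track, path) {
  readr::write_tsv(tibble::tibble(chrom = track$chrom,
                                  pos_1based = track$pos + 1L,
                                  depth = track$depth), path)
  invisible(path)
}

#' Read repeat-mask intervals from a BED file
#'
#' @param path Path to a BED3+ file (0-based half-open, as BED).
#' @return A tibble with columns `chrom`, `start`, `end` and, when a fourth
#'   column is present, `name`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(track|browser|#)", lines)]
  if (length(lines) == 0)
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer()))
  f <- strsplit(lines, "\t", fixed = TRUE)
  m <- do.call(rbind, lapply(f, function(x) x[1:max(3, min(lengths(f)))]))
  out <- tibble::tibble(chrom = m[, 1], start = as.integer(m[, 2]),
                        end = as.integer(m[, 3]))
  if (ncol(m) >= 4) out$name <- m[, 4]
  out
}

#' Write intervals to a BED file
#'
#' @param x Tibble with columns `chrom`, `start`, `end` (0-based half-open)
#'   and optionally `name`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  if (!is.null(x$name))
    writeLines(sprintf("%s\t%d\t%d\t%s", x$chrom, x$start, x$end, x$name),
               path)
  else
    writeLines(sprintf("%s\t%d\t%d", x$chrom, x$start, x$end), path)
  invisible(path)
}
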