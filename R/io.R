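# Readers and writers for the pipeline's tabular interchange formats:
# mosdepth summary TSV, PAF / nucmer show-coords -T / BLAST outfmt 6
# alignments, fai-style length tables, BED, and provenance-stamped TSVs.

provenance_line <- function(stage, params = list()) {
  p <- paste(names(params), vapply(params, function(v) paste(format(v), collapse = ","),
                                   character(1)), sep = "=", collapse = " ")
  digest <- sprintf("%08x", sum(utf8ToInt(p)) %% .Machine$integer.max)
  sprintf("# sexscaff %s stage=%s params_hash=%s",
          as.character(utils::packageVersion("sexscaff")), stage, digest)
}

#' Write a TSV with a provenance comment header
#'
#' All stage outputs carry a first line `# sexscaff <version> stage=<name>
#' params_hash=<hash>` so a table can always be traced to the parameters that
#' produced it. Read such files back with [read_stage_tsv()].
#'
#' @param df data frame to write.
#' @param path output path.
#' @param stage stage name recorded in the header.
#' @param params named list of parameter values hashed into the header.
#' @return invisibly, `path`.
#' @export
write_stage_tsv <- function(df, path, stage, params = list()) {
  con <- file(path, open = "w")
  on.exit(close(con))
  writeLines(provenance_line(stage, params), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_stage_tsv
#' @export
read_stage_tsv <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}

#' Read a mosdepth summary file
#'
#' Expects the mosdepth `*.mosdepth.summary.txt` dialect: a header line
#' `chrom length bases mean min max`, one row per sequence, optional
#' `<chrom>_region` rows (ignored) and a `total` row (excluded from the
#' per-scaffold records but kept as the `"total"` attribute for QC).
#'
#' @param path file path.
#' @param sample_sex `"male"` or `"female"`, recorded on every row.
#' @return depth-summary tibble (`scaffold_id`, `length`, `mean_depth`,
#'   `sample_sex`) with attribute `"total"`.
#' @export
read_mosdepth_summary <- function(path, sample_sex) {
  sample_sex <- match.arg(sample_sex, c("male", "female"))
  if (!file.exists(path)) stop_input("depth summary not found: %s", path)
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("chrom", "length", "mean")
  if (!all(need %in% names(raw))) {
    stop_input("%s is not a mosdepth summary (missing columns: %s)", path,
               paste(setdiff(need, names(raw)), collapse = ", "))
  }
  total <- raw[raw$chrom == "total", , drop = FALSE]
  keep <- raw$chrom != "total" & !grepl("_region$", raw$chrom)
  out <- tibble::tibble(
    scaffold_id = raw$chrom[keep],
    length = as.numeric(raw$length[keep]),
    mean_depth = as.numeric(raw$mean[keep]),
    sample_sex = sample_sex
  )
  attr(out, "total") <- total
  out
}

#' @rdname read_mosdepth_summary
#' @param depths a depth-summary tibble (e.g. from [simulate_depths()]).
#' @export
write_mosdepth_summary <- function(depths, path) {
  bases <- round(depths$mean_depth * depths$length)
  df <- data.frame(
    chrom = depths$scaffold_id,
    length = format(depths$length, scientific = FALSE, trim = TRUE),
    bases = format(bases, scientific = FALSE, trim = TRUE),
    mean = sprintf("%.4f", depths$mean_depth),
    min = 0L,
    max = format(round(depths$mean_depth * 2), scientific = FALSE, trim = TRUE)
  )
  total <- data.frame(
    chrom = "total",
    length = format(sum(depths$length), scientific = FALSE, trim = TRUE),
    bases = format(sum(bases), scientific = FALSE, trim = TRUE),
    mean = sprintf("%.4f", sum(bases) / sum(depths$length)),
    min = 0L, max = max(df$max)
  )
  utils::write.table(rbind(df, total), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read scaffold lengths from a fai-style table
#'
#' Uses the first two columns (sequence name, length) of a `samtools faidx`
#' index or any headerless TSV with that layout.
#'
#' @param path file path.
#' @return tibble (`scaffold_id`, `length`).
#' @export
read_fai <- function(path) {
  if (!file.exists(path)) stop_input("length table not found: %s", path)
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  tibble::tibble(scaffold_id = as.character(raw[[1]]),
                 length = as.numeric(raw[[2]]))
}

#' Parse scaffold-to-chromosome alignments
#'
#' Supports three tabular dialects. PAF is already 0-based half-open; nucmer
#' `show-coords -T` and BLAST outfmt 6 are 1-based inclusive and may have
#' start > end on the reverse strand — both are normalized to 0-based
#' half-open query intervals with `q_start < q_end` (strand is irrelevant for
#' occupancy-based assignment). For nucmer the reference is the chromosome
#' (first tag) and the query the scaffold (second tag); for BLAST the query
#' is the scaffold and the subject the chromosome.
#'
#' @param path file path.
#' @param dialect one of `"paf"`, `"nucmer_coords"`, `"blast6"`.
#' @return alignment-hit tibble (`scaffold_id`, `q_start`, `q_end`,
#'   `chromosome`, `t_start`, `t_end`, `aligned_len`, `identity`).
#' @export
parse_alignments <- function(path, dialect = c("paf", "nucmer_coords", "blast6")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_input("alignment file not found: %s", path)
  lines <- readLines(path)
  lines_idx <- seq_along(lines)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lines <- lines[keep]; lines_idx <- lines_idx[keep]
  if (dialect == "nucmer_coords") {
    # show-coords -T prefixes the table with file paths, "NUCMER" and a
    # bracketed column-header line; data rows start with a number
    is_data <- grepl("^-?[0-9]", lines)
    lines <- lines[is_data]; lines_idx <- lines_idx[is_data]
  }
  if (length(lines) == 0) {
    return(tibble::tibble(scaffold_id = character(), q_start = numeric(),
                          q_end = numeric(), chromosome = character(),
                          t_start = numeric(), t_end = numeric(),
                          aligned_len = numeric(), identity = numeric()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  min_cols <- c(paf = 12L, nucmer_coords = 9L, blast6 = 12L)[[dialect]]
  bad <- which(lengths(fields) < min_cols)
  if (length(bad) > 0) {
    stop_input("unparseable %s row(s) at line(s) %s of %s (< %d columns)",
               dialect, paste(utils::head(lines_idx[bad], 5), collapse = ", "),
               path, min_cols)
  }
  get <- function(i) vapply(fields, `[[`, character(1), i)
  num <- function(i) {
    v <- suppressWarnings(as.numeric(get(i)))
    if (anyNA(v)) {
      stop_input("non-numeric value in column %d at line(s) %s of %s", i,
                 paste(utils::head(lines_idx[is.na(v)], 5), collapse = ", "),
                 path)
    }
    v
  }
  out <- switch(dialect,
    paf = tibble::tibble(
      scaffold_id = get(1), q_start = num(3), q_end = num(4),
      chromosome = get(6), t_start = num(8), t_end = num(9),
      aligned_len = num(11), identity = num(10) / pmax(num(11), 1)
    ),
    nucmer_coords = {
      s1 <- num(1); e1 <- num(2); s2 <- num(3); e2 <- num(4)
      ntags <- lengths(fields)
      tibble::tibble(
        scaffold_id = vapply(fields, function(f) f[[length(f)]], character(1)),
        q_start = pmin(s2, e2) - 1, q_end = pmax(s2, e2),
        chromosome = vapply(fields, function(f) f[[length(f) - 1L]], character(1)),
        t_start = pmin(s1, e1) - 1, t_end = pmax(s1, e1),
        identity = num(7) / 100
      )
    },
    blast6 = {
      qs <- num(7); qe <- num(8)
      tibble::tibble(
        scaffold_id = get(1), q_start = pmin(qs, qe) - 1, q_end = pmax(qs, qe),
        chromosome = get(2), t_start = pmin(num(9), num(10)) - 1,
        t_end = pmax(num(9), num(10)), identity = num(3) / 100
      )
    }
  )
  out$aligned_len <- out$q_end - out$q_start
  if (any(out$q_start >= out$q_end)) {
    stop_input("alignment with non-positive query interval at line(s) %s of %s",
               paste(utils::head(lines_idx[out$q_start >= out$q_end], 5),
                     collapse = ", "), path)
  }
  out[, c("scaffold_id", "q_start", "q_end", "chromosome", "t_start", "t_end",
          "aligned_len", "identity")]
}

#' @rdname parse_alignments
#' @param hits alignment-hit tibble (0-based half-open query coordinates).
#' @param truth,config simulation truth and config, used for query/target
#'   sequence lengths in the PAF columns.
#' @export
write_paf <- function(hits, truth, config, path) {
  qlen <- setNames(truth$length, truth$scaffold_id)
  tlen <- config$chrom_lengths
  alen <- hits$q_end - hits$q_start
  df <- data.frame(
    qname = hits$scaffold_id,
    qlen = format(qlen[hits$scaffold_id], scientific = FALSE, trim = TRUE),
    qstart = format(hits$q_start, scientific = FALSE, trim = TRUE),
    qend = format(hits$q_end, scientific = FALSE, trim = TRUE),
    strand = "+",
    tname = hits$chromosome,
    tlen = format(unlist(tlen[hits$chromosome]), scientific = FALSE, trim = TRUE),
    tstart = format(hits$t_start, scientific = FALSE, trim = TRUE),
    tend = format(hits$t_end, scientific = FALSE, trim = TRUE),
    nmatch = format(round(hits$identity * alen), scientific = FALSE, trim = TRUE),
    alen = format(alen, scientific = FALSE, trim = TRUE),
    mapq = 60L
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read and write marker-gene hits (BLAST outfmt 6 + manifest)
#'
#' The hits file is standard 12-column BLAST outfmt 6 with the gene as query
#' and the scaffold as subject; the manifest is a 3-column TSV
#' (`gene`, `gene_class` in \{Y_GENE, HOMOLOG\}, `partner_gene`) linking each
#' Y gene to its X/autosomal homolog. Coordinates stay 1-based inclusive.
#'
#' @param hits_path BLAST outfmt 6 file.
#' @param manifest_path gene manifest TSV.
#' @return marker-hit tibble with manifest columns joined.
#' @export
read_marker_hits <- function(hits_path, manifest_path) {
  if (!file.exists(hits_path)) stop_input("marker hits not found: %s", hits_path)
  if (!file.exists(manifest_path)) {
    stop_input("gene manifest not found: %s", manifest_path)
  }
  cols <- c("gene", "scaffold_id", "pident", "aln_len", "mismatch", "gapopen",
            "q_start", "q_end", "s_start", "s_end", "evalue", "bitscore")
  raw <- utils::read.table(hits_path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, col.names = cols)
  manifest <- readr::read_tsv(manifest_path, show_col_types = FALSE,
                              progress = FALSE)
  need <- c("gene", "gene_class", "partner_gene")
  if (!all(need %in% names(manifest))) {
    stop_input("manifest must have columns %s", paste(need, collapse = ", "))
  }
  missing <- setdiff(unique(raw$gene), manifest$gene)
  if (length(missing) > 0) {
    stop_input("gene(s) in hits absent from manifest: %s",
               paste(missing, collapse = ", "))
  }
  dplyr::left_join(tibble::as_tibble(raw), manifest, by = "gene")[,
    c("gene", "gene_class", "partner_gene", "scaffold_id", "pident",
      "aln_len", "mismatch", "gapopen", "q_start", "q_end", "s_start",
      "s_end", "evalue", "bitscore")]
}

#' @rdname read_marker_hits
#' @param hits marker-hit tibble (e.g. from [simulate_marker_hits()]).
#' @param path output path.
#' @export
write_blast6 <- function(hits, path) {
  df <- data.frame(
    qseqid = hits$gene, sseqid = hits$scaffold_id, pident = hits$pident,
    length = hits$aln_len, mismatch = hits$mismatch, gapopen = hits$gapopen,
    qstart = hits$q_start, qend = hits$q_end, sstart = hits$s_start,
    send = hits$s_end, evalue = format(hits$evalue, digits = 3),
    bitscore = hits$bitscore
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write scaffold labels as BED
#'
#' One row per scaffold over its whole extent (0-based half-open), name =
#' assigned chromosome / label, score encoding provenance (BOTH 1000,
#' HOMOLOGY_ONLY 750, COVERAGE_ONLY 500, CONFLICT 250, NONE 0).
#'
#' @param labels tibble with `scaffold_id`, `length`, `label` and optional
#'   `provenance` columns.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_bed <- function(labels, path) {
  score_map <- c(BOTH = 1000L, HOMOLOGY_ONLY = 750L, COVERAGE_ONLY = 500L,
                 CONFLICT = 250L, NONE = 0L)
  score <- if ("provenance" %in% names(labels)) {
    unname(score_map[labels$provenance])
  } else 0L
  df <- data.frame(
    chrom = labels$scaffold_id,
    start = 0L,
    end = format(labels$length, scientific = FALSE, trim = TRUE),
    name = labels$label,
    score = ifelse(is.na(score), 0L, score),
    strand = "."
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
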