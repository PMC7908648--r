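# Result serialization: annotated variant TSV, structural-variant VCF 4.2,
# IGV session XML, and the QC report with cohort z-scores.

VARIANT_TABLE_COLS <- c(
  "id", "chrom", "start", "end", "svtype", "length", "caller", "cnv",
  "sample_id", "gt", "copy_number", "tranche", "su", "sr", "dp",
  "dra", "drf", "avg_mq", "avg_mq_bp", "gc", "cr", "segdup",
  "pafsu", "pafdra", "pafv", "paf1kg", "pafg", "rare",
  "genes", "candg", "ia", "iua", "dgv"
)

#' Write the annotated variant table
#'
#' One row per variant per carrier sample, 1-based inclusive coordinates,
#' stable column order. Missing annotation columns are filled with `NA`.
#'
#' @param variants Data frame of per-variant annotations (wide, one row
#'   per variant).
#' @param samples Per-sample evidence data frame (`id`, `sample_id`, read
#'   counts, DOC metrics, genotype).
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_variant_table <- function(variants, samples, path) {
  tab <- flatten_variants(variants, samples)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' One row per variant per carrier sample, stable column set
#' @noRd
flatten_variants <- function(variants, samples) {
  if (nrow(variants) == 0) {
    tab <- as.data.frame(stats::setNames(
      rep(list(character(0)), length(VARIANT_TABLE_COLS)), VARIANT_TABLE_COLS))
    return(tab)
  }
  per_sample <- intersect(c("sample_id", "gt", "copy_number", "su", "sr",
                            "dp", "dra", "drf"), names(samples))
  tab <- merge(variants, samples[, c("id", per_sample), drop = FALSE],
               by = "id", suffixes = c("", ".smp"), all.x = TRUE)
  tab$length <- tab$end - tab$start + 1
  for (cl in setdiff(VARIANT_TABLE_COLS, names(tab))) tab[[cl]] <- NA
  tab <- tab[order(tab$chrom, tab$start, tab$sample_id), VARIANT_TABLE_COLS]
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(x) ifelse(is.finite(x), signif(x, 6), x))
  rownames(tab) <- NULL
  tab
}

#' @rdname write_variant_table
#' @export
read_variant_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = "NA", check.names = FALSE)
}

#' Write integrated variants as a structural-variant VCF 4.2
#'
#' Symbolic ALT records (`<DEL>`, `<DUP>`, `<INV>`) with SVTYPE/END/SVLEN,
#' CNV state, tranche, PAFs and RARE in INFO, and per-sample GT:SU:SR:DP
#' FORMAT fields.
#'
#' @param variants Wide per-variant data frame (as for
#'   [write_variant_table()]).
#' @param samples Per-sample evidence data frame.
#' @param path Output VCF path.
#' @param contig_lengths Named vector for `##contig` header lines.
#' @return The path, invisibly.
#' @export
write_vcf <- function(variants, samples, path, contig_lengths = NULL) {
  sample_ids <- sort(unique(samples$sample_id))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=svintegrate",
    "##ALT=<ID=DEL,Description=\"Deletion\">",
    "##ALT=<ID=DUP,Description=\"Duplication\">",
    "##ALT=<ID=INV,Description=\"Inversion\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
    "##INFO=<ID=CNV,Number=1,Type=Integer,Description=\"Copy number variant flag\">",
    "##INFO=<ID=TRANCHE,Number=1,Type=String,Description=\"Confidence tranche\">",
    "##INFO=<ID=PAFSU,Number=1,Type=Float,Description=\"PAF from control DP+SR evidence\">",
    "##INFO=<ID=PAFDRA,Number=1,Type=Float,Description=\"PAF from control read-depth concordance\">",
    "##INFO=<ID=PAFV,Number=1,Type=Float,Description=\"PAF from called control variants\">",
    "##INFO=<ID=PAF1KG,Number=1,Type=Float,Description=\"PAF from external reference set\">",
    "##INFO=<ID=RARE,Number=1,Type=Integer,Description=\"Rare flag\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=SU,Number=1,Type=Integer,Description=\"Supporting reads\">",
    "##FORMAT=<ID=SR,Number=1,Type=Integer,Description=\"Split reads\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Discordant pairs\">"
  )
  if (!is.null(contig_lengths)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contig_lengths), as.integer(contig_lengths)))
  }
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", sample_ids),
                      collapse = "\t"))
  fmt_num <- function(x) ifelse(is.na(x), ".", format(signif(x, 6), trim = TRUE,
                                                      scientific = FALSE))
  rows <- character(0)
  if (nrow(variants)) {
    variants <- variants[order(variants$chrom, variants$start), , drop = FALSE]
    rows <- vapply(seq_len(nrow(variants)), function(i) {
      v <- variants[i, ]
      info <- sprintf("SVTYPE=%s;END=%d;SVLEN=%d;CNV=%d;TRANCHE=%s",
                      v$svtype, v$end,
                      (v$end - v$start + 1) * ifelse(v$svtype == "DEL", -1L, 1L),
                      as.integer(isTRUE(v$cnv)), v$tranche %||% "LOW")
      for (p in c("pafsu", "pafdra", "pafv", "paf1kg")) {
        if (!is.null(v[[p]]) && !is.na(v[[p]])) {
          info <- paste0(info, sprintf(";%s=%s", toupper(p), fmt_num(v[[p]])))
        }
      }
      if (!is.null(v$rare)) {
        info <- paste0(info, sprintf(";RARE=%d", as.integer(isTRUE(v$rare))))
      }
      sm <- samples[samples$id == v$id, , drop = FALSE]
      gts <- vapply(sample_ids, function(s) {
        r <- sm[sm$sample_id == s, , drop = FALSE]
        if (nrow(r) == 0) return("0/0:.:.:.")
        sprintf("%s:%d:%d:%d", r$gt[1] %||% "./.",
                as.integer(r$su[1]), as.integer(r$sr[1]), as.integer(r$dp[1]))
      }, character(1))
      paste(c(v$chrom, v$start, v$id, "N", sprintf("<%s>", v$svtype), ".",
              "PASS", info, "GT:SU:SR:DP", gts), collapse = "\t")
    }, character(1))
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}

IGV_TRACKS <- c("control_doc", "sample_doc", "mq", "doc_sd",
                "segdup", "sv_calls", "dp", "sr", "control_calls", "dgv",
                "genes")

#' Build an IGV session file
#'
#' Writes a session XML referencing the 11 standard review tracks: control
#' depth of coverage, sample DOC (rendered either over all reads or
#' restricted to MQ >= 20), average mapping quality, population coverage
#' SD, segmental duplications, the integrated SV calls, discordant pairs,
#' split reads, control-cohort calls, known-variant database records and
#' gene models.
#'
#' @param paths Named list/vector mapping each of
#'   `r paste(IGV_TRACKS, collapse = ", ")` to a resource path.
#' @param genome Genome id written into the session (default "custom").
#' @param path Output XML path.
#' @return The path, invisibly.
#' @export
build_igv_session <- function(paths, genome = "custom", path) {
  missing <- setdiff(IGV_TRACKS, names(paths))
  if (length(missing)) {
    stopf("missing IGV track path(s): %s", paste(missing, collapse = ", "))
  }
  doc <- xml2::xml_new_root("Session", genome = genome, version = "8")
  res <- xml2::xml_add_child(doc, "Resources")
  for (tr in IGV_TRACKS) {
    xml2::xml_add_child(res, "Resource", path = as.character(paths[[tr]]))
  }
  panel <- xml2::xml_add_child(doc, "Panel", name = "DataPanel")
  for (tr in IGV_TRACKS) {
    xml2::xml_add_child(panel, "Track", id = as.character(paths[[tr]]),
                        name = tr)
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' QC report with control-cohort z-scores
#'
#' For each metric, z = (x - mean) / sd against the control distribution;
#' metrics with |z| > 2 are flagged. The sample passes QC when at most
#' `max_flagged_fraction` of metrics with defined z-scores are flagged
#' ("most metrics within |z| <= 2"). A zero control SD leaves z undefined
#' and flags the metric for review.
#'
#' @param metrics Named numeric vector of sample QC metrics.
#' @param control_dist Data frame `metric`, `mean`, `sd` (optionally `n`).
#' @param max_flagged_fraction Pass threshold (default 0.5).
#' @param html_path Optional path; when given, a small HTML report is
#'   rendered there.
#' @return List of class `qc_report`: `table` (metric, value, mean, sd, z,
#'   flagged), `pass`.
#' @export
qc_report <- function(metrics, control_dist, max_flagged_fraction = 0.5,
                      html_path = NULL) {
  need_cols(control_dist, c("metric", "mean", "sd"), "control distribution")
  tab <- data.frame(metric = names(metrics), value = as.numeric(metrics),
                    stringsAsFactors = FALSE)
  idx <- match(tab$metric, control_dist$metric)
  tab$mean <- control_dist$mean[idx]
  tab$sd <- control_dist$sd[idx]
  tab$z <- ifelse(is.na(tab$sd) | tab$sd == 0, NA_real_,
                  (tab$value - tab$mean) / tab$sd)
  tab$flagged <- is.na(tab$z) | abs(tab$z) > 2
  defined <- !is.na(idx)
  pass <- mean(tab$flagged[defined]) <= max_flagged_fraction
  out <- structure(list(table = tab, pass = pass), class = "qc_report")
  if (!is.null(html_path)) {
    rows <- sprintf(
      "<tr%s><td>%s</td><td>%.4g</td><td>%.4g</td><td>%.4g</td><td>%s</td></tr>",
      ifelse(tab$flagged, " class='flag'", ""), tab$metric, tab$value,
      tab$mean, tab$sd, ifelse(is.na(tab$z), "n/a", sprintf("%.2f", tab$z)))
    html <- c("<html><head><style>.flag{background:#fdd}</style></head><body>",
              sprintf("<h1>QC report: %s</h1>",
                      ifelse(pass, "PASS", "REVIEW")),
              "<table border='1'><tr><th>metric</th><th>value</th>",
              "<th>control mean</th><th>control sd</th><th>z</th></tr>",
              rows, "</table></body></html>")
    writeLines(html, html_path)
  }
  out
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: %s (%d/%d metrics flagged)\n",
              ifelse(x$pass, "PASS", "REVIEW"), sum(x$table$flagged),
              nrow(x$table)))
  invisible(x)
}
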