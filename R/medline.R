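#' Parse a MEDLINE flat-file export
#'
#' Reads the tagged flat-file format produced by PubMed's "MEDLINE" export:
#' records separated by blank lines, fields as `TAG - value` with
#' continuation lines indented by spaces. Fields used: `PMID` (id), `TI`
#' (title), `AB` (abstract), `MH` (MeSH headings, one per line), `JT`
#' (journal title), `DP` (date of publication; the leading 4-digit year is
#' taken), `IP`/`VI` (issue/volume; `IP` preferred, else `VI`).
#'
#' MEDLINE files carry no newsworthiness label; pass `default_label` to
#' [read_corpus()] when importing.
#'
#' @param path Path to a MEDLINE-format text file.
#' @return A tibble of citation rows (`label` all `NA`).
#' @keywords internal
read_medline <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ## split into records on blank lines
  blank <- !nzchar(trimws(lines))
  rec_id <- cumsum(c(TRUE, blank[-length(blank)])) # advances after each blank
  recs <- split(lines[!blank], rec_id[!blank])
  rows <- lapply(recs, parse_medline_record)
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0L) return(tibble::tibble())
  out <- do.call(rbind, rows)
  out$label <- NA_character_ # MEDLINE carries no label; see default_label
  out
}

parse_medline_record <- function(lines) {
  ## fold continuation lines (leading whitespace) into the preceding field
  tags <- character(0)
  vals <- character(0)
  for (ln in lines) {
    if (grepl("^[A-Z0-9]{1,4}\\s*- ", ln)) {
      tags <- c(tags, trimws(sub("^([A-Z0-9]{1,4})\\s*- .*$", "\\1", ln)))
      vals <- c(vals, sub("^[A-Z0-9]{1,4}\\s*- ", "", ln))
    } else if (length(vals) > 0L && grepl("^\\s+", ln)) {
      vals[length(vals)] <- paste(vals[length(vals)], trimws(ln))
    }
  }
  if (length(tags) == 0L || !"PMID" %in% tags) return(NULL)
  first_val <- function(tag) {
    i <- which(tags == tag)
    if (length(i) == 0L) "" else vals[i[1L]]
  }
  year <- suppressWarnings(as.integer(sub("^.*?(\\d{4}).*$", "\\1",
                                          first_val("DP"))))
  issue <- first_val("IP")
  if (!nzchar(issue)) issue <- first_val("VI")
  citation_record(
    id = first_val("PMID"),
    title = first_val("TI"),
    abstract = first_val("AB"),
    mesh_terms = vals[tags == "MH"],
    journal = first_val("JT"),
    year = year,
    issue = issue,
    label = "unlabeled",
    source_tag = "medline"
  )
}
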