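#' Pathway specification
#'
#' A pathway is either a single element (auto-recurrence of its series) or a
#' zinc-centred pair (cross-recurrence of zinc against a partner element;
#' zinc is a central regulator of other metals, so co-regulation is always
#' tested against it).
#'
#' @param singles Character vector of element symbols analysed individually.
#' @param zinc_partners Character vector of partner symbols for the
#'   zinc-pair cross-recurrences.
#' @return A data frame with columns `kind` (`SINGLE`/`ZINC_PAIR`),
#'   `element`, `partner` (`NA` for singles) and `label` (`"Co"`,
#'   `"Zn-Cu"`, ...).
#' @export
pathway_spec <- function(singles = character(), zinc_partners = character()) {
  if (length(singles) + length(zinc_partners) == 0L) {
    stop("empty pathway list", call. = FALSE)
  }
  rbind(
    if (length(singles)) data.frame(kind = "SINGLE", element = singles,
                                    partner = NA_character_, label = singles,
                                    stringsAsFactors = FALSE),
    if (length(zinc_partners)) data.frame(kind = "ZINC_PAIR", element = "Zn",
                                          partner = zinc_partners,
                                          label = paste0("Zn-", zinc_partners),
                                          stringsAsFactors = FALSE)
  )
}

#' Default pathway set: 8 single elements and 7 zinc pairs
#'
#' Singles Zn, Cu, Pb, Co, V, Li, Sn, Mn and zinc pairs Zn-Cu, Zn-Pb, Zn-Co,
#' Zn-V, Zn-Li, Zn-Sn, Zn-Ca, giving the standard 15 pathways and, with the
#' four line-based measures, a 60-column feature table.
#'
#' @return A pathway data frame (see [pathway_spec()]).
#' @export
default_pathways <- function() {
  pathway_spec(singles = c("Zn", "Cu", "Pb", "Co", "V", "Li", "Sn", "Mn"),
               zinc_partners = c("Cu", "Pb", "Co", "V", "Li", "Sn", "Ca"))
}

rqa_measures <- c("DET", "MDL", "ENTR", "RT")

#' Cohort feature table: four dynamical measures per pathway
#'
#' Runs recurrence quantification over every subject and pathway: single
#' pathways use the auto-recurrence matrix of that element's series, zinc
#' pairs the zinc-partner cross-recurrence matrix.  Series that are missing,
#' too short (fewer than `params$min_embedded` embedded points), or
#' degenerate yield missing cells — never errors — and every missing cell is
#' recorded with its cause in the attached log.
#'
#' @param series_df Long series table (`subject_id`, `element`, `day`,
#'   `ratio`).
#' @param subjects Subject table; only `subject_id` is used here.
#' @param pathways Pathway data frame, default [default_pathways()].
#' @param params [embedding_params()] shared by all matrices.
#' @return A data frame with `subject_id` plus one column per
#'   (pathway, measure), named `<label>_<measure>` (e.g. `Zn-Cu_ENTR`).
#'   Attribute `"log"` holds a data frame of missing cells and causes.
#' @export
compute_feature_table <- function(series_df, subjects,
                                  pathways = default_pathways(),
                                  params = embedding_params()) {
  if (is.null(pathways) || nrow(pathways) == 0L) stop("empty pathway list", call. = FALSE)
  ids <- subjects$subject_id
  cols <- as.vector(t(outer(pathways$label, rqa_measures, paste, sep = "_")))
  tab <- as.data.frame(matrix(NA_real_, nrow = length(ids), ncol = length(cols),
                              dimnames = list(NULL, cols)))
  log <- list()
  note <- function(id, label, reason) {
    log[[length(log) + 1L]] <<- data.frame(subject_id = id, pathway = label,
                                           reason = reason, stringsAsFactors = FALSE)
  }
  min_pts <- params$min_embedded + (params$m - 1L) * params$tau
  # index the long table once; repeated per-cell scans dominate at cohort scale
  key <- paste(series_df$subject_id, series_df$element, sep = "\r")
  idx <- split(seq_len(nrow(series_df)), key)
  lookup <- function(id, element) {
    rows <- idx[[paste(id, element, sep = "\r")]]
    if (is.null(rows)) return(NULL)
    o <- order(series_df$day[rows])
    new_element_series(id, element, series_df$day[rows][o], series_df$ratio[rows][o])
  }
  for (i in seq_along(ids)) {
    id <- ids[i]
    for (p in seq_len(nrow(pathways))) {
      label <- pathways$label[p]
      feats <- tryCatch({
        if (pathways$kind[p] == "SINGLE") {
          s <- lookup(id, pathways$element[p])
          if (is.null(s)) stop(sprintf("no %s series", pathways$element[p]), call. = FALSE)
          if (length(s$values) < min_pts) stop("series too short", call. = FALSE)
          rqa(s, params)
        } else {
          a <- lookup(id, pathways$element[p])
          b <- lookup(id, pathways$partner[p])
          if (is.null(a)) stop(sprintf("no %s series", pathways$element[p]), call. = FALSE)
          if (is.null(b)) stop(sprintf("no %s series", pathways$partner[p]), call. = FALSE)
          if (min(length(a$values), length(b$values)) < min_pts) {
            stop("series too short", call. = FALSE)
          }
          crqa(a, b, params)
        }
      }, error = function(e) {
        note(id, label, conditionMessage(e))
        NULL
      })
      if (!is.null(feats)) {
        tab[i, paste(label, rqa_measures, sep = "_")] <-
          unlist(feats[rqa_measures])
        for (msr in rqa_measures) {
          if (is.na(feats[[msr]])) note(id, label, paste(msr, "undefined (empty histogram)"))
        }
      }
    }
  }
  out <- cbind(data.frame(subject_id = ids, stringsAsFactors = FALSE), tab)
  attr(out, "log") <- if (length(log)) do.call(rbind, log) else
    data.frame(subject_id = character(), pathway = character(), reason = character())
  out
}

# split "Zn-Cu_ENTR" into pathway and measure
split_feature_name <- function(x) {
  measure <- sub("^.*_", "", x)
  pathway <- sub("_[^_]*$", "", x)
  data.frame(feature = x, pathway = pathway, measure = measure,
             stringsAsFactors = FALSE)
}

feature_columns <- function(table) setdiff(names(table), "subject_id")
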