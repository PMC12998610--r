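#' Build a linkage summary across subjects
#'
#' The linkage summary pairs a subject metadata table with each subject's
#' inferred linkage sets; it is the input to the differential cell signaling
#' test.
#'
#' @param entries Named list of [infer_subject()] results (names = subject
#'   ids), or an unnamed list whose elements carry `$subject`.
#' @param meta Data frame with a `subject` column plus grouping variables;
#'   every subject in `entries` must be present.
#' @return A `linkage_summary`: list with `subjects` (ordered ids), `meta`
#'   (data frame, rows in subject order) and `linkages` (named list of
#'   `subject_linkages`).
#' @export
build_summary <- function(entries, meta) {
  if (is.null(names(entries))) {
    names(entries) <- vapply(entries, function(e) e$subject, character(1))
  }
  subjects <- names(entries)
  if (anyDuplicated(subjects)) {
    .stop_input(sprintf(
      "duplicate subject id(s): %s",
      paste(unique(subjects[duplicated(subjects)]), collapse = ", ")
    ))
  }
  if (!is.data.frame(meta) || !("subject" %in% names(meta))) {
    .stop_input("meta must be a data frame with a 'subject' column")
  }
  missing <- setdiff(subjects, meta$subject)
  if (length(missing)) {
    .stop_input(sprintf(
      "subject(s) missing from meta: %s", paste(missing, collapse = ", ")
    ))
  }
  meta <- meta[match(subjects, meta$subject), , drop = FALSE]
  rownames(meta) <- NULL
  structure(
    list(subjects = subjects, meta = meta, linkages = entries),
    class = "linkage_summary"
  )
}

#' @export
print.linkage_summary <- function(x, ...) {
  cat(sprintf(
    "linkage_summary: %d subject(s); meta variables: %s\n",
    length(x$subjects),
    paste(setdiff(names(x$meta), "subject"), collapse = ", ")
  ))
  invisible(x)
}

.LINKAGE_CLASSES <- c("tfs", "rec", "incoming_lig", "tfs_rec", "cl_rec_lig")

.as_linkage_key <- function(linkage) {
  if (length(linkage) > 1) do.call(.join_key, as.list(linkage)) else linkage
}

#' Count subjects with and without a linkage, per group
#'
#' @param s A [build_summary()] result.
#' @param linkage_class One of `"tfs"`, `"rec"`, `"incoming_lig"`,
#'   `"tfs_rec"`, `"cl_rec_lig"`.
#' @param linkage Linkage key, either a single `"a|b|..."` string or a
#'   character vector of fields.
#' @param group_var Name of a metadata variable.
#' @param subjects Optional subject subset to count over.
#' @return Data frame with columns `group`, `n_with`, `n_without` (group
#'   levels with zero subjects omitted).
#' @export
count_linkage <- function(s, linkage_class, linkage, group_var,
                          subjects = NULL) {
  stopifnot(inherits(s, "linkage_summary"))
  if (!(linkage_class %in% .LINKAGE_CLASSES)) {
    .stop_input(sprintf("unknown linkage class: %s", linkage_class))
  }
  if (!(group_var %in% names(s$meta))) {
    .stop_input(sprintf("unknown grouping variable: %s", group_var))
  }
  subjects <- subjects %||% s$subjects
  unknown <- setdiff(subjects, s$subjects)
  if (length(unknown)) {
    .stop_input(sprintf(
      "unknown subject(s): %s", paste(unknown, collapse = ", ")
    ))
  }
  key <- .as_linkage_key(linkage)
  groups <- s$meta[[group_var]][match(subjects, s$subjects)]
  has <- vapply(subjects, function(sub) {
    key %in% s$linkages[[sub]][[linkage_class]]
  }, logical(1))
  levels <- unique(groups)
  out <- data.frame(
    group = levels,
    n_with = vapply(levels, function(g) sum(has[groups == g]), integer(1)),
    n_without = vapply(levels, function(g) sum(!has[groups == g]), integer(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Unique linkages incoming to a cell type
#'
#' Union, over all subjects, of the linkages of one class whose recipient
#' cell type matches, in deterministic lexicographic order.
#'
#' @inheritParams count_linkage
#' @param cell_type Recipient cell type label.
#' @return Sorted character vector of linkage keys.
#' @export
unique_linkages <- function(s, linkage_class, cell_type) {
  stopifnot(inherits(s, "linkage_summary"))
  if (!(linkage_class %in% .LINKAGE_CLASSES)) {
    .stop_input(sprintf("unknown linkage class: %s", linkage_class))
  }
  all_keys <- unique(unlist(lapply(s$linkages, `[[`, linkage_class)))
  if (length(all_keys) == 0) return(character())
  first <- vapply(.split_key(all_keys), `[[`, character(1), 1)
  sort(all_keys[first == cell_type])
}

#' Linkage summary from external interaction-probability tables
#'
#' Adapter for cell-cell communication methods that emit per-subject
#' interaction probabilities (e.g. CellChat). An intercellular linkage is
#' active when its probability is strictly greater than `threshold`
#' (default 0.1); `rec` and `incoming_lig` are derived by projection, and
#' the intracellular sets are left empty (such methods provide none).
#'
#' @param tables Named list (subject -> data frame) with columns `source`,
#'   `target`, `ligand`, `receptor`, `prob`.
#' @param threshold Activity threshold on the probability (strict `>`).
#' @param meta Subject metadata data frame (see [build_summary()]).
#' @return A `linkage_summary`.
#' @export
from_interaction_scores <- function(tables, threshold = 0.1, meta) {
  entries <- lapply(names(tables), function(sub) {
    tab <- tables[[sub]]
    need <- c("source", "target", "ligand", "receptor", "prob")
    absent <- setdiff(need, names(tab))
    if (length(absent)) {
      .stop_input(sprintf(
        "interaction table for %s missing column(s): %s",
        sub, paste(absent, collapse = ", ")
      ))
    }
    if (any(tab$prob < 0 | tab$prob > 1)) {
      .stop_input(sprintf(
        "interaction probabilities for %s must lie in [0, 1]", sub
      ))
    }
    act <- tab[tab$prob > threshold, , drop = FALSE]
    cl <- sort(unique(.join_key(act$target, act$receptor, act$ligand,
                                act$source)))
    structure(
      list(
        subject = sub,
        cell_types = sort(unique(c(tab$source, tab$target))),
        tfs = character(),
        rec = sort(unique(.join_key(act$target, act$receptor))),
        incoming_lig = sort(unique(.join_key(act$target, act$ligand))),
        tfs_rec = character(),
        cl_rec_lig = cl
      ),
      class = "subject_linkages"
    )
  })
  names(entries) <- names(tables)
  build_summary(entries, meta)
}

#' Write / read a linkage summary as JSON
#'
#' Lossless round trip: subject order, metadata and all linkage sets are
#' preserved (sets are stored as sorted arrays for diff-stability). Unknown
#' extra keys in a file are accepted with a warning.
#'
#' @param s A `linkage_summary`.
#' @param path JSON file path.
#' @return `read_summary` returns a `linkage_summary`; `write_summary`
#'   returns `path` invisibly.
#' @export
write_summary <- function(s, path) {
  stopifnot(inherits(s, "linkage_summary"))
  obj <- list(
    schema = "linksig-summary-1",
    subjects = s$subjects,
    meta = s$meta,
    linkages = lapply(s$linkages, function(l) {
      list(
        subject = l$subject,
        cell_types = l$cell_types,
        tfs = l$tfs,
        rec = l$rec,
        incoming_lig = l$incoming_lig,
        tfs_rec = l$tfs_rec,
        cl_rec_lig = l$cl_rec_lig
      )
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       dataframe = "rows", digits = NA)
  invisible(path)
}

#' @rdname write_summary
#' @export
read_summary <- function(path) {
  obj <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) {
      .stop_parse(sprintf("cannot parse %s: %s", path, conditionMessage(e)))
    }
  )
  need <- c("subjects", "meta", "linkages")
  absent <- setdiff(need, names(obj))
  if (length(absent)) {
    .stop_parse(sprintf(
      "%s: missing key(s) at JSON root: %s", path,
      paste(absent, collapse = ", ")
    ))
  }
  extra <- setdiff(names(obj), c("schema", need))
  if (length(extra)) {
    warning(sprintf(
      "ignoring unknown key(s) in %s: %s", path, paste(extra, collapse = ", ")
    ))
  }
  chr <- function(x) as.character(unlist(x) %||% character())
  meta <- do.call(rbind, lapply(obj$meta, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  entries <- lapply(obj$linkages, function(l) {
    structure(
      list(
        subject = l$subject,
        cell_types = chr(l$cell_types),
        tfs = chr(l$tfs),
        rec = chr(l$rec),
        incoming_lig = chr(l$incoming_lig),
        tfs_rec = chr(l$tfs_rec),
        cl_rec_lig = chr(l$cl_rec_lig)
      ),
      class = "subject_linkages"
    )
  })
  names(entries) <- as.character(unlist(obj$subjects))
  build_summary(entries, meta)
}
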