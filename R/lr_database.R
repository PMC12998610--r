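#' Construct a ligand-receptor interaction database
#'
#' An `lr_database` stores named ligand-receptor interactions where either side
#' may be a heteromeric complex (an ordered list of gene symbols). It is the
#' reference used by [infer_subject()] to assemble intercellular linkages.
#'
#' @param id Character vector of unique interaction identifiers.
#' @param ligand_name,receptor_name Character vectors naming each side
#'   (a gene symbol for single-gene partners, a complex name otherwise).
#' @param ligand_components,receptor_components Lists of character vectors of
#'   gene symbols; each must be non-empty and free of duplicates.
#' @param source Character vector (recycled) labelling the database of origin.
#'
#' @return An object of class `lr_database` with an `interactions` data frame
#'   (list columns for the complex components).
#' @export
lr_database <- function(id, ligand_name, receptor_name,
                        ligand_components, receptor_components,
                        source = "custom") {
  n <- length(id)
  stopifnot(
    length(ligand_name) == n, length(receptor_name) == n,
    length(ligand_components) == n, length(receptor_components) == n
  )
  if (anyDuplicated(id)) {
    .stop_input("interaction ids must be unique within a database")
  }
  check_complex <- function(comps, what) {
    bad <- vapply(comps, function(g) {
      length(g) == 0 || anyNA(g) || anyDuplicated(g) > 0
    }, logical(1))
    if (any(bad)) {
      .stop_input(sprintf(
        "%s complexes must be non-empty with unique gene symbols (%d offending)",
        what, sum(bad)
      ))
    }
  }
  check_complex(ligand_components, "ligand")
  check_complex(receptor_components, "receptor")
  interactions <- data.frame(
    id = as.character(id),
    ligand_name = as.character(ligand_name),
    receptor_name = as.character(receptor_name),
    source = rep_len(as.character(source), n),
    stringsAsFactors = FALSE
  )
  interactions$ligand_components <- lapply(ligand_components, as.character)
  interactions$receptor_components <- lapply(receptor_components, as.character)
  structure(list(interactions = interactions), class = "lr_database")
}

#' @export
print.lr_database <- function(x, ...) {
  cat(sprintf(
    "lr_database: %d interactions, %d genes (%s)\n",
    nrow(x$interactions), length(lr_gene_universe(x)),
    paste(unique(x$interactions$source), collapse = ", ")
  ))
  invisible(x)
}

#' Gene universe of a ligand-receptor database
#'
#' @param db An `lr_database`.
#' @return Sorted character vector of all gene symbols appearing in any
#'   ligand or receptor complex.
#' @export
lr_gene_universe <- function(db) {
  stopifnot(inherits(db, "lr_database"))
  sort(unique(c(
    unlist(db$interactions$ligand_components),
    unlist(db$interactions$receptor_components)
  )))
}

# Dedup key: sorted component tuples on each side.
.lr_pair_key <- function(db) {
  vapply(seq_len(nrow(db$interactions)), function(i) {
    paste(
      paste(sort(db$interactions$ligand_components[[i]]), collapse = "+"),
      paste(sort(db$interactions$receptor_components[[i]]), collapse = "+"),
      sep = "->"
    )
  }, character(1))
}

.normalize_symbols <- function(x, normalize_case) {
  switch(normalize_case,
    none = x,
    human = toupper(x),
    mouse = paste0(
      toupper(substr(x, 1, 1)),
      tolower(substr(x, 2, nchar(x)))
    )
  )
}

#' Load a CellPhoneDB-style ligand-receptor database
#'
#' Reads the four flat CSV tables of the CellPhoneDB v4 layout
#' (`interaction_input.csv`, `complex_input.csv`, `protein_input.csv`,
#' `gene_input.csv`) and resolves every interaction partner to gene symbols.
#' Complex partners are expanded through the complex table; protein partners
#' are mapped to gene symbols through the gene table, expanding to all genes
#' when a protein maps to several. Interactions with a partner that cannot be
#' resolved to at least one gene are dropped and the drop count is reported
#' via `message()` and the `"n_dropped"` attribute.
#'
#' @param dir_path Directory containing the four CSV tables.
#' @param normalize_case `"none"` (default, case-sensitive symbols), `"human"`
#'   (upper-case) or `"mouse"` (title-case).
#' @return An [lr_database()].
#' @export
load_cellphonedb <- function(dir_path,
                             normalize_case = c("none", "human", "mouse")) {
  normalize_case <- match.arg(normalize_case)
  files <- c(
    interactions = "interaction_input.csv",
    complexes = "complex_input.csv",
    proteins = "protein_input.csv",
    genes = "gene_input.csv"
  )
  paths <- file.path(dir_path, files)
  names(paths) <- names(files)
  missing <- !file.exists(paths)
  if (any(missing)) {
    .stop_input(sprintf(
      "missing required CellPhoneDB file(s): %s",
      paste(files[missing], collapse = ", ")
    ))
  }
  inter <- .read_table(paths[["interactions"]])
  cplx <- .read_table(paths[["complexes"]])
  prot <- .read_table(paths[["proteins"]])
  gene <- .read_table(paths[["genes"]])

  need <- function(tab, cols, file) {
    absent <- setdiff(cols, names(tab))
    if (length(absent)) {
      .stop_parse(sprintf(
        "malformed header in %s: missing column(s) %s",
        file, paste(absent, collapse = ", ")
      ))
    }
  }
  need(inter, c("partner_a", "partner_b"), files[["interactions"]])
  need(cplx, "complex_name", files[["complexes"]])
  need(gene, c("gene_name", "uniprot"), files[["genes"]])
  need(prot, "uniprot", files[["proteins"]])

  gene$gene_name <- .normalize_symbols(gene$gene_name, normalize_case)
  genes_of_protein <- split(gene$gene_name, gene$uniprot)
  member_cols <- grep("^uniprot_[0-9]+$", names(cplx), value = TRUE)
  complex_members <- lapply(seq_len(nrow(cplx)), function(i) {
    m <- unlist(cplx[i, member_cols], use.names = FALSE)
    m[!is.na(m) & nzchar(m)]
  })
  names(complex_members) <- cplx$complex_name

  resolve <- function(partner) {
    if (partner %in% names(complex_members)) {
      comps <- unique(unlist(lapply(
        complex_members[[partner]],
        function(u) genes_of_protein[[u]]
      )))
      if (length(comps) == 0 ||
        length(comps) < length(complex_members[[partner]])) {
        return(NULL) # an unresolvable member invalidates the complex
      }
      return(list(name = partner, components = comps))
    }
    g <- genes_of_protein[[partner]]
    if (!is.null(g) && length(g) > 0) {
      return(list(name = if (length(g) == 1) g else partner,
                  components = unique(g)))
    }
    # fall back: partner annotated directly as a gene symbol
    if (partner %in% gene$gene_name) {
      return(list(name = partner, components = partner))
    }
    NULL
  }

  ids <- if ("id_cp_interaction" %in% names(inter)) {
    inter$id_cp_interaction
  } else {
    paste(inter$partner_a, inter$partner_b, sep = "_")
  }
  keep <- list()
  n_dropped <- 0L
  for (i in seq_len(nrow(inter))) {
    lig <- resolve(inter$partner_a[i])
    rec <- resolve(inter$partner_b[i])
    if (is.null(lig) || is.null(rec)) {
      n_dropped <- n_dropped + 1L
      next
    }
    keep[[length(keep) + 1L]] <- list(
      id = ids[i], lig = lig, rec = rec
    )
  }
  if (n_dropped > 0) {
    message(sprintf(
      "load_cellphonedb: dropped %d interaction(s) with unresolvable partners",
      n_dropped
    ))
  }
  db <- lr_database(
    id = vapply(keep, `[[`, character(1), "id"),
    ligand_name = vapply(keep, function(k) k$lig$name, character(1)),
    receptor_name = vapply(keep, function(k) k$rec$name, character(1)),
    ligand_components = lapply(keep, function(k) k$lig$components),
    receptor_components = lapply(keep, function(k) k$rec$components),
    source = "cellphonedb"
  )
  attr(db, "n_dropped") <- n_dropped
  db
}

#' Load a two-column ligand/receptor pairs table
#'
#' Generic adapter for single-gene-per-side databases such as CellTalkDB
#' exports. Duplicate (ligand, receptor) rows are collapsed to one
#' interaction.
#'
#' @param path Delimited text file (CSV/TSV by extension) with a header.
#' @param ligand_col,receptor_col Names of the ligand and receptor columns.
#' @param source Origin label stored on each interaction.
#' @return An [lr_database()].
#' @export
load_pairs_table <- function(path, ligand_col = "ligand",
                             receptor_col = "receptor",
                             source = "pairs_table") {
  tab <- .read_table(path)
  absent <- setdiff(c(ligand_col, receptor_col), names(tab))
  if (length(absent)) {
    .stop_input(sprintf(
      "column(s) not found in %s: %s", path, paste(absent, collapse = ", ")
    ))
  }
  lig <- as.character(tab[[ligand_col]])
  rec <- as.character(tab[[receptor_col]])
  dup <- duplicated(paste(lig, rec, sep = "\r"))
  lig <- lig[!dup]
  rec <- rec[!dup]
  lr_database(
    id = paste(lig, rec, sep = "_"),
    ligand_name = lig,
    receptor_name = rec,
    ligand_components = as.list(lig),
    receptor_components = as.list(rec),
    source = source
  )
}

#' Merge two ligand-receptor databases
#'
#' Takes the union of interactions. Two interactions with identical sorted
#' component sets on both sides are collapsed, keeping the entry (and id)
#' from `a`.
#'
#' @param a,b `lr_database` objects.
#' @return An [lr_database()].
#' @export
merge_databases <- function(a, b) {
  stopifnot(inherits(a, "lr_database"), inherits(b, "lr_database"))
  if (nrow(b$interactions) == 0) return(a)
  if (nrow(a$interactions) == 0) return(b)
  keep_b <- !(.lr_pair_key(b) %in% .lr_pair_key(a))
  ints_b <- b$interactions[keep_b, , drop = FALSE]
  # disambiguate id collisions between sources
  clash <- ints_b$id %in% a$interactions$id
  ints_b$id[clash] <- paste0(ints_b$id[clash], ".", ints_b$source[clash])
  merged <- rbind(a$interactions, ints_b)
  rownames(merged) <- NULL
  structure(list(interactions = merged), class = "lr_database")
}

#' Write / read the canonical JSON serialization of a database
#'
#' @param db An `lr_database`.
#' @param path Output (or input) JSON file.
#' @return `read_lr_database` returns an [lr_database()];
#'   `write_lr_database` returns `path` invisibly.
#' @export
write_lr_database <- function(db, path) {
  stopifnot(inherits(db, "lr_database"))
  recs <- lapply(seq_len(nrow(db$interactions)), function(i) {
    list(
      id = db$interactions$id[i],
      ligand_name = db$interactions$ligand_name[i],
      receptor_name = db$interactions$receptor_name[i],
      ligand_components = db$interactions$ligand_components[[i]],
      receptor_components = db$interactions$receptor_components[[i]],
      source = db$interactions$source[i]
    )
  })
  jsonlite::write_json(
    list(schema = "linksig-lrdb-1", interactions = recs),
    path,
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_lr_database
#' @export
read_lr_database <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$interactions)) {
    .stop_parse(sprintf("%s: not a linksig database file ($interactions)", path))
  }
  recs <- obj$interactions
  lr_database(
    id = vapply(recs, function(r) r$id, character(1)),
    ligand_name = vapply(recs, function(r) r$ligand_name, character(1)),
    receptor_name = vapply(recs, function(r) r$receptor_name, character(1)),
    ligand_components = lapply(recs, function(r) unlist(r$ligand_components)),
    receptor_components = lapply(recs, function(r) unlist(r$receptor_components)),
    source = vapply(recs, function(r) r$source %||% "unknown", character(1))
  )
}
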