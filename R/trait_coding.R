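# Categorical trait tables, fuzzy (multi-valued) binary coding, functional
# entities.

canonical_label <- function(x) tolower(trimws(x))

#' Build a validated species-by-trait table
#'
#' A trait table holds, for every species, a non-empty set of category labels
#' for each categorical trait. Cells may carry several categories (fuzzy
#' coding), e.g. a barracuda occupying near-surface, mid-water and near-bottom
#' positions at once. Labels are matched against the declared category sets
#' after trimming whitespace and case-folding; the declared spelling is kept
#' for output.
#'
#' @param data data.frame with one row per species: a species id column, one
#'   column per trait (multi-valued cells separated by `delim`), and optional
#'   taxonomy columns.
#' @param traits character vector of trait column names. Defaults to every
#'   column that is neither the species column nor a taxonomy column.
#' @param schema optional named list `trait -> character vector of declared
#'   categories` fixing category order. When `NULL`, categories are declared
#'   in order of first appearance in `data`.
#' @param delim delimiter separating categories inside a cell.
#' @param species_col name of the species id column.
#' @param taxonomy_cols optional character vector naming taxonomy columns
#'   (e.g. `c("genus", "family")`).
#' @return An object of class `trait_table`: a list with elements `species`,
#'   `schema`, `assignments` (per species, a named list of category vectors)
#'   and `taxonomy` (data.frame or `NULL`).
#' @examples
#' df <- data.frame(species = c("sp1", "sp2"),
#'                  diet = c("planktivore", "piscivore; invertivore"),
#'                  size = c("small", "large"))
#' tt <- trait_table(df)
#' tt$assignments$sp2$diet
#' @export
trait_table <- function(data, traits = NULL, schema = NULL, delim = ";",
                        species_col = "species", taxonomy_cols = NULL) {
  stopifnot(is.data.frame(data))
  if (!species_col %in% names(data)) {
    stop("column '", species_col, "' not found in trait data", call. = FALSE)
  }
  species <- as.character(data[[species_col]])
  if (anyDuplicated(species)) {
    stop("duplicated species ids: ",
         paste(unique(species[duplicated(species)]), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(traits)) {
    traits <- setdiff(names(data), c(species_col, taxonomy_cols))
  }
  missing_tr <- setdiff(traits, names(data))
  if (length(missing_tr)) {
    stop("trait column(s) not found: ", paste(missing_tr, collapse = ", "),
         call. = FALSE)
  }

  split_cell <- function(cell) {
    if (is.na(cell)) return(character(0))
    out <- trimws(strsplit(as.character(cell), delim, fixed = TRUE)[[1]])
    out[nzchar(out)]
  }

  raw <- lapply(traits, function(tr) lapply(data[[tr]], split_cell))
  names(raw) <- traits

  if (is.null(schema)) {
    schema <- lapply(traits, function(tr) {
      labs <- unlist(raw[[tr]], use.names = FALSE)
      labs[!duplicated(canonical_label(labs))]
    })
    names(schema) <- traits
  } else {
    if (!all(traits %in% names(schema))) {
      stop("schema must declare every trait in `traits`", call. = FALSE)
    }
    schema <- schema[traits]
  }

  assignments <- vector("list", length(species))
  names(assignments) <- species
  for (i in seq_along(species)) {
    per_trait <- vector("list", length(traits))
    names(per_trait) <- traits
    for (tr in traits) {
      labs <- raw[[tr]][[i]]
      if (!length(labs)) {
        stop("species '", species[i], "' has no category for trait '", tr,
             "'", call. = FALSE)
      }
      idx <- match(canonical_label(labs), canonical_label(schema[[tr]]))
      if (anyNA(idx)) {
        stop("unknown category '", labs[which(is.na(idx))[1]],
             "' for trait '", tr, "' (species '", species[i], "')",
             call. = FALSE)
      }
      per_trait[[tr]] <- schema[[tr]][sort(unique(idx))]
    }
    assignments[[i]] <- per_trait
  }

  taxonomy <- NULL
  if (!is.null(taxonomy_cols)) {
    missing_tax <- setdiff(taxonomy_cols, names(data))
    if (length(missing_tax)) {
      stop("taxonomy column(s) not found: ",
           paste(missing_tax, collapse = ", "), call. = FALSE)
    }
    taxonomy <- data.frame(species = species, data[taxonomy_cols],
                           stringsAsFactors = FALSE, row.names = NULL)
  }

  structure(list(species = species, schema = schema,
                 assignments = assignments, taxonomy = taxonomy),
            class = "trait_table")
}

#' @export
print.trait_table <- function(x, ...) {
  cat("Trait table:", length(x$species), "species,",
      length(x$schema), "traits\n")
  for (tr in names(x$schema)) {
    cat("  ", tr, " (", length(x$schema[[tr]]), " categories)\n", sep = "")
  }
  invisible(x)
}

#' Expand a trait table into a weighted binary trait matrix
#'
#' Each trait is spread into as many 0/1 columns as it has categories; a
#' species scores 1 in every category it was assigned. To keep traits with
#' many categories from dominating downstream distances, every column of a
#' trait with `k` categories receives weight `1/k`, so each trait contributes
#' total weight 1.
#'
#' @param table a [trait_table()].
#' @param traits traits to include, in the declared order by default.
#'   Excluding a trait (sensitivity analysis) drops its columns; remaining
#'   weights are untouched.
#' @return A numeric species x category matrix of class `binary_trait_matrix`
#'   with attributes `trait`, `category` (per column) and `weights`.
#' @examples
#' df <- data.frame(species = c("a", "b", "c"),
#'                  t1 = c("x", "y", "z"), t2 = c("u", "v", "u"))
#' m <- expand_traits(trait_table(df))
#' attr(m, "weights")  # 1/3,1/3,1/3,1/2,1/2
#' @export
expand_traits <- function(table, traits = NULL) {
  stopifnot(inherits(table, "trait_table"))
  if (is.null(traits)) traits <- names(table$schema)
  unknown <- setdiff(traits, names(table$schema))
  if (length(unknown)) {
    stop("trait(s) not in table: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  col_trait <- unlist(lapply(traits, function(tr) {
    rep(tr, length(table$schema[[tr]]))
  }))
  col_cat <- unlist(lapply(traits, function(tr) table$schema[[tr]]))
  weights <- unlist(lapply(traits, function(tr) {
    k <- length(table$schema[[tr]])
    rep(1 / k, k)
  }))

  n <- length(table$species)
  m <- matrix(0, n, length(col_cat),
              dimnames = list(table$species,
                              paste(col_trait, col_cat, sep = "::")))
  for (i in seq_len(n)) {
    asg <- table$assignments[[i]]
    for (tr in traits) {
      labs <- asg[[tr]]
      if (is.null(labs) || !length(labs)) {
        stop("species '", table$species[i], "' has no category for trait '",
             tr, "'", call. = FALSE)
      }
      j <- which(col_trait == tr)[match(labs, table$schema[[tr]])]
      m[i, j] <- 1
    }
  }
  structure(m, trait = col_trait, category = col_cat, weights = weights,
            class = c("binary_trait_matrix", "matrix", "array"))
}

#' Collapse a binary trait matrix back to category sets
#'
#' Inverse of [expand_traits()]; used mainly to verify the encoding round
#' trip.
#'
#' @param matrix a `binary_trait_matrix`.
#' @return A named list (per species) of named lists (per trait) of category
#'   labels.
#' @export
collapse_traits <- function(matrix) {
  col_trait <- attr(matrix, "trait")
  col_cat <- attr(matrix, "category")
  traits <- unique(col_trait)
  lapply(seq_len(nrow(matrix)), function(i) {
    out <- lapply(traits, function(tr) {
      j <- which(col_trait == tr & matrix[i, ] == 1)
      col_cat[j]
    })
    names(out) <- traits
    out
  }) |> stats::setNames(rownames(matrix))
}

#' Derive functional entities from a binary trait matrix
#'
#' Species sharing an identical binary trait profile form one functional
#' entity, the unit at which trait combinations are counted: each trait
#' combination enters functional analyses once however many species carry it.
#' Entity ids are assigned along the lexicographic order of the binary
#' signatures, so they are stable under permutation of the input rows.
#'
#' @param matrix a `binary_trait_matrix`.
#' @return An object of class `functional_entities`: list with `entity`
#'   (named character, species -> entity id), `members` (named list, entity id
#'   -> character vector of species) and `signature` (named character, entity
#'   id -> 0/1 string).
#' @export
derive_entities <- function(matrix) {
  sig <- apply(matrix, 1, paste0, collapse = "")
  uniq <- sort(unique(sig))
  ids <- sprintf("FE%0*d", max(3L, nchar(length(uniq))), seq_along(uniq))
  names(ids) <- uniq
  entity <- ids[sig]
  names(entity) <- rownames(matrix)
  members <- split(rownames(matrix), entity)
  members <- members[ids]
  signature <- stats::setNames(uniq, ids)
  structure(list(entity = entity, members = members, signature = signature),
            class = "functional_entities")
}

#' @export
print.functional_entities <- function(x, ...) {
  cat("Functional entities:", length(x$members), "entities from",
      length(x$entity), "species\n")
  invisible(x)
}

#' Taxonomic redundancy of functional entities
#'
#' Counts the species, genera and families carried by each functional entity,
#' ranked by species count (ties broken alphabetically by entity id). High
#' counts flag ecological roles buffered against species loss.
#'
#' @param entities a [derive_entities()] result.
#' @param taxonomy data.frame with columns `species`, `genus`, `family`, or
#'   `NULL` to count species only (with a warning).
#' @return data.frame with columns `entity_id`, `n_species`, and (when
#'   taxonomy is available) `n_genera`, `n_families`.
#' @export
entity_redundancy <- function(entities, taxonomy = NULL) {
  stopifnot(inherits(entities, "functional_entities"))
  ids <- names(entities$members)
  n_species <- vapply(entities$members, length, integer(1))
  out <- data.frame(entity_id = ids, n_species = n_species,
                    stringsAsFactors = FALSE, row.names = NULL)
  all_sp <- unlist(entities$members, use.names = FALSE)
  have_tax <- !is.null(taxonomy) && all(all_sp %in% taxonomy$species)
  if (!have_tax) {
    if (!is.null(taxonomy)) {
      warning("taxonomy missing for some species; counting species only")
    } else {
      warning("no taxonomy supplied; counting species only")
    }
  } else {
    gi <- match(all_sp, taxonomy$species)
    tax <- taxonomy[gi, ]
    lookup <- stats::setNames(seq_along(all_sp), all_sp)
    out$n_genera <- vapply(entities$members, function(sp) {
      length(unique(tax$genus[lookup[sp]]))
    }, integer(1))
    out$n_families <- vapply(entities$members, function(sp) {
      length(unique(tax$family[lookup[sp]]))
    }, integer(1))
  }
  out <- out[order(-out$n_species, out$entity_id), ]
  rownames(out) <- NULL
  out
}
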