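#' @title Multi-environment trial phenotypes and diallel crossing plans
#' @description I/O and validation for the two tabular inputs of the
#'   pipeline: a tidy long-format phenotype table (one row per plot x
#'   trait) and a crossing plan listing parents (with male/female roles)
#'   and the realized F1 combinations.
#' @name trial-data
NULL

.pheno_cols <- c("genotype", "role", "location", "year", "replicate",
                 "block", "trait", "value")

#' Read a phenotype table
#'
#' Reads a comma-separated phenotype file with columns
#' \code{genotype,role,location,year,replicate,block,trait,value} and
#' validates it against a trait registry: unknown traits are rejected,
#' visual-score values must lie within their 1-9 bounds, and duplicated
#' (genotype, location, year, replicate, trait) keys are an error.
#' Missing plots are simply absent rows.
#'
#' @param path path to a CSV file (UTF-8, "." decimal separator). Lines
#'   starting with \code{#} are ignored.
#' @param traits trait registry (see [trait_registry()]).
#' @return A validated data frame of plot records.
#' @seealso [write_phenotype_table()], [validate_design()]
#' @export
read_phenotype_table <- function(path, traits = trait_registry()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                         fileEncoding = "UTF-8")
  validate_phenotypes(tab, traits)
}

#' Validate an in-memory phenotype table
#'
#' @param tab data frame with the phenotype columns.
#' @param traits trait registry.
#' @return the table, with typed columns, invisibly checked.
#' @export
validate_phenotypes <- function(tab, traits = trait_registry()) {
  missing_cols <- setdiff(.pheno_cols, names(tab))
  if (length(missing_cols)) {
    stop("phenotype table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tab <- tab[, .pheno_cols]
  tab$genotype <- as.character(tab$genotype)
  tab$role <- as.character(tab$role)
  tab$location <- as.character(tab$location)
  tab$year <- as.integer(tab$year)
  tab$replicate <- as.integer(tab$replicate)
  tab$block <- as.integer(tab$block)
  tab$trait <- as.character(tab$trait)
  tab$value <- as.numeric(tab$value)

  bad_role <- !tab$role %in% c("parent", "hybrid")
  if (any(bad_role)) {
    stop("invalid role at row(s) ", paste(utils::head(which(bad_role), 5),
         collapse = ", "), ": must be 'parent' or 'hybrid'", call. = FALSE)
  }
  unknown <- setdiff(unique(tab$trait), traits$name)
  if (length(unknown)) {
    stop("unknown trait(s) not in registry: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(tab$value))) {
    stop("non-finite value at row(s) ",
         paste(utils::head(which(!is.finite(tab$value)), 5), collapse = ", "),
         call. = FALSE)
  }
  idx <- match(tab$trait, traits$name)
  lo <- traits$scale_min[idx]
  hi <- traits$scale_max[idx]
  oob <- !is.na(lo) & (tab$value < lo | tab$value > hi)
  if (any(oob)) {
    stop("score value outside scale bounds at row(s) ",
         paste(utils::head(which(oob), 5), collapse = ", "),
         " (trait ", tab$trait[which(oob)[1]], ", bounds ",
         lo[which(oob)[1]], "-", hi[which(oob)[1]], ")", call. = FALSE)
  }
  key <- paste(tab$genotype, tab$location, tab$year, tab$replicate,
               tab$trait, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicated (genotype, location, year, replicate, trait) key at row ",
         which(duplicated(key))[1], call. = FALSE)
  }
  tab
}

#' Write a phenotype table
#'
#' Inverse of [read_phenotype_table()]; round-trips records exactly.
#'
#' @param tab phenotype data frame.
#' @param path output CSV path.
#' @param header_lines optional character vector of comment lines
#'   (written with a leading \code{#}).
#' @return the path, invisibly.
#' @export
write_phenotype_table <- function(tab, path, header_lines = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (length(header_lines)) writeLines(paste0("# ", header_lines), con)
  utils::write.csv(tab[, .pheno_cols], con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a crossing plan
#'
#' A crossing plan declares the parent roster (ids and male/female
#' roles, optional pedigree text) and the realized F1 combinations.
#' Every cross must reference declared parents of the matching role and
#' no (female, male) pair may be duplicated.
#'
#' @param parents data frame with columns \code{id}, \code{sex_role}
#'   ("male"/"female") and optionally \code{pedigree}.
#' @param crosses data frame with columns \code{female_id},
#'   \code{male_id} and optionally \code{hybrid_id}; missing hybrid ids
#'   default to \code{"FEMALE/MALE"}.
#' @return An object of class \code{crossing_plan}: a list with elements
#'   \code{parents} and \code{crosses}.
#' @export
#' @examples
#' crossing_plan(
#'   parents = data.frame(id = c("A", "B"), sex_role = c("female", "male")),
#'   crosses = data.frame(female_id = "A", male_id = "B")
#' )
crossing_plan <- function(parents, crosses) {
  parents <- as.data.frame(parents, stringsAsFactors = FALSE)
  crosses <- as.data.frame(crosses, stringsAsFactors = FALSE)
  if (!all(c("id", "sex_role") %in% names(parents))) {
    stop("parents needs columns id, sex_role", call. = FALSE)
  }
  if (is.null(parents$pedigree)) parents$pedigree <- ""
  parents$id <- as.character(parents$id)
  if (!all(parents$sex_role %in% c("male", "female"))) {
    stop("sex_role must be 'male' or 'female'", call. = FALSE)
  }
  if (anyDuplicated(parents$id)) {
    stop("duplicated parent id(s): ",
         paste(unique(parents$id[duplicated(parents$id)]), collapse = ", "),
         call. = FALSE)
  }
  if (!all(c("female_id", "male_id") %in% names(crosses)) ||
      nrow(crosses) < 1) {
    stop("crosses needs >= 1 row with columns female_id, male_id",
         call. = FALSE)
  }
  crosses$female_id <- as.character(crosses$female_id)
  crosses$male_id <- as.character(crosses$male_id)
  if (is.null(crosses$hybrid_id)) {
    crosses$hybrid_id <- paste(crosses$female_id, crosses$male_id, sep = "/")
  }
  crosses$hybrid_id <- as.character(crosses$hybrid_id)
  crosses <- crosses[, c("hybrid_id", "female_id", "male_id")]

  undeclared <- setdiff(c(crosses$female_id, crosses$male_id), parents$id)
  if (length(undeclared)) {
    stop("cross references undeclared parent(s): ",
         paste(undeclared, collapse = ", "), call. = FALSE)
  }
  role <- stats::setNames(parents$sex_role, parents$id)
  if (any(role[crosses$female_id] != "female")) {
    stop("female_id refers to a parent not declared as female", call. = FALSE)
  }
  if (any(role[crosses$male_id] != "male")) {
    stop("male_id refers to a parent not declared as male", call. = FALSE)
  }
  pair <- paste(crosses$female_id, crosses$male_id, sep = "\r")
  if (anyDuplicated(pair)) {
    stop("duplicated (female, male) pair: ",
         sub("\r", " x ", pair[duplicated(pair)][1]), call. = FALSE)
  }
  if (anyDuplicated(crosses$hybrid_id)) {
    stop("duplicated hybrid_id", call. = FALSE)
  }
  structure(list(parents = parents, crosses = crosses),
            class = "crossing_plan")
}

#' @export
print.crossing_plan <- function(x, ...) {
  nm <- sum(x$parents$sex_role == "male")
  nf <- sum(x$parents$sex_role == "female")
  cat("Crossing plan:", nm, "males x", nf, "females,",
      nrow(x$crosses), "of", nm * nf, "possible crosses realized\n")
  invisible(x)
}

#' Read a crossing plan file
#'
#' The file is a single CSV with a \code{record} column taking values
#' \code{parent} (uses columns \code{id}, \code{sex_role},
#' \code{pedigree}) and \code{cross} (uses \code{hybrid_id},
#' \code{female_id}, \code{male_id}).
#'
#' @param path CSV path.
#' @return a [crossing_plan()] object.
#' @export
read_crossing_plan <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                         fileEncoding = "UTF-8")
  if (!"record" %in% names(tab)) {
    stop("crossing plan file needs a 'record' column (parent/cross)",
         call. = FALSE)
  }
  p <- tab[tab$record == "parent", , drop = FALSE]
  x <- tab[tab$record == "cross", , drop = FALSE]
  if (is.null(p$pedigree)) p$pedigree <- ""
  crossing_plan(
    parents = p[, intersect(c("id", "sex_role", "pedigree"), names(p))],
    crosses = x[, intersect(c("hybrid_id", "female_id", "male_id"), names(x))]
  )
}

#' Write a crossing plan file
#' @param plan a [crossing_plan()] object.
#' @param path output CSV path.
#' @param header_lines optional comment lines.
#' @return the path, invisibly.
#' @export
write_crossing_plan <- function(plan, path, header_lines = NULL) {
  p <- plan$parents
  x <- plan$crosses
  out <- data.frame(
    record = c(rep("parent", nrow(p)), rep("cross", nrow(x))),
    id = c(p$id, rep("", nrow(x))),
    sex_role = c(p$sex_role, rep("", nrow(x))),
    pedigree = c(p$pedigree, rep("", nrow(x))),
    hybrid_id = c(rep("", nrow(p)), x$hybrid_id),
    female_id = c(rep("", nrow(p)), x$female_id),
    male_id = c(rep("", nrow(p)), x$male_id),
    stringsAsFactors = FALSE
  )
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (length(header_lines)) writeLines(paste0("# ", header_lines), con)
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Incidence matrix of parents in crosses
#'
#' Rows are crosses, columns are parents; each row has a 1 in its
#' female's and its male's column. This is the design structure through
#' which general combining ability (GCA) effects enter the model.
#'
#' @param plan a crossing plan.
#' @return numeric matrix (crosses x parents) with dimnames.
#' @keywords internal
parent_incidence <- function(plan) {
  ids <- plan$parents$id
  Z <- matrix(0, nrow(plan$crosses), length(ids),
              dimnames = list(plan$crosses$hybrid_id, ids))
  Z[cbind(seq_len(nrow(Z)), match(plan$crosses$female_id, ids))] <- 1
  Z[cbind(seq_len(nrow(Z)), match(plan$crosses$male_id, ids))] <- 1
  Z
}

#' Connected components of the crossing graph
#'
#' Parents are nodes; each realized cross joins its two parents.
#' Components are found by breadth-first search. Parents appearing in no
#' cross form their own singleton components.
#'
#' @param plan crossing plan.
#' @return integer vector of component labels, named by parent id.
#' @keywords internal
crossing_components <- function(plan) {
  ids <- plan$parents$id
  comp <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  adj <- lapply(stats::setNames(ids, ids), function(i) character(0))
  for (k in seq_len(nrow(plan$crosses))) {
    f <- plan$crosses$female_id[k]
    m <- plan$crosses$male_id[k]
    adj[[f]] <- c(adj[[f]], m)
    adj[[m]] <- c(adj[[m]], f)
  }
  label <- 0L
  for (s in ids) {
    if (!is.na(comp[s])) next
    label <- label + 1L
    queue <- s
    comp[s] <- label
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      nb <- adj[[v]][is.na(comp[adj[[v]]])]
      comp[nb] <- label
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Check agreement and estimability of a trial design
#'
#' Cross-checks a phenotype table against a crossing plan: which
#' genotypes are missing on either side, how many plots each environment
#' contributes, whether any parent appears in no cross, and whether the
#' male x female incidence is connected so that all GCA contrasts are
#' estimable. The check is purely reporting; inputs are not modified.
#'
#' @param tab phenotype table.
#' @param plan crossing plan.
#' @return an object of class \code{design_report}.
#' @export
validate_design <- function(tab, plan) {
  expected <- c(plan$parents$id, plan$crosses$hybrid_id)
  observed <- unique(tab$genotype)
  comp <- crossing_components(plan)
  in_cross <- plan$parents$id %in%
    c(plan$crosses$female_id, plan$crosses$male_id)
  env <- paste(tab$location, tab$year, sep = ":")
  rep_counts <- as.data.frame(table(environment = env), stringsAsFactors = FALSE)
  names(rep_counts)[2] <- "n_plots"
  n_comp_active <- length(unique(comp[plan$parents$id[in_cross]]))
  report <- list(
    missing_from_table = setdiff(expected, observed),
    missing_from_plan = setdiff(observed, expected),
    replication = rep_counts,
    parents_without_crosses = plan$parents$id[!in_cross],
    n_components = n_comp_active + sum(!in_cross),
    components = comp,
    gca_estimable = all(in_cross) && n_comp_active == 1L
  )
  structure(report, class = "design_report")
}

#' @export
print.design_report <- function(x, ...) {
  cat("Design report\n")
  cat("  genotypes missing from table:", length(x$missing_from_table), "\n")
  cat("  genotypes missing from plan: ", length(x$missing_from_plan), "\n")
  cat("  parents without crosses:     ",
      if (length(x$parents_without_crosses))
        paste(x$parents_without_crosses, collapse = ", ") else "none", "\n")
  cat("  crossing-graph components:   ", x$n_components, "\n")
  cat("  GCA contrasts estimable:     ", x$gca_estimable, "\n")
  invisible(x)
}
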