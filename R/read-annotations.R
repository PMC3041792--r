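#' Read a GMT gene-set collection
#'
#' Parses the Broad GMT dialect: one set per line, tab-separated fields
#' `name`, `description`, then gene ids. Without a supplied universe the
#' universe is the union of all genes in the file, sorted lexicographically
#' for reproducibility; with one, genes outside it are dropped (counted in a
#' message) and universe order is kept.
#'
#' @param path Path to a GMT file.
#' @param universe Optional character vector of gene ids fixing the universe.
#' @param case_fold If `TRUE`, gene ids (and the universe) are upper-cased
#'   before matching. Matching is otherwise exact; no alias resolution.
#' @return An [annotation_matrix()].
#' @export
read_gmt <- function(path, universe = NULL, case_fold = FALSE) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) abort("Empty GMT file.")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad) > 0) {
    abort(sprintf("Malformed GMT line %d: fewer than 3 tab-separated fields.",
                  bad[1]))
  }
  set_names <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(set_names)) {
    abort(sprintf("Duplicate set name in GMT: %s",
                  set_names[duplicated(set_names)][1]))
  }
  genes_per_set <- lapply(fields, function(f) unique(f[-(1:2)]))
  if (case_fold) {
    genes_per_set <- lapply(genes_per_set, toupper)
    if (!is.null(universe)) universe <- toupper(universe)
  }
  all_genes <- sort(unique(unlist(genes_per_set)))
  if (is.null(universe)) {
    uni <- all_genes
  } else {
    uni <- as.character(universe)
    n_drop <- length(setdiff(all_genes, uni))
    if (n_drop > 0) {
      inform(sprintf(
        "read_gmt: %d gene id(s) in the file are absent from the universe and were dropped.",
        n_drop
      ))
    }
  }
  m <- matrix(FALSE, length(uni), length(set_names),
              dimnames = list(uni, set_names))
  for (j in seq_along(genes_per_set)) {
    g <- intersect(genes_per_set[[j]], uni)
    m[g, j] <- TRUE
  }
  annotation_matrix(m)
}

#' Write an annotation matrix to GMT
#'
#' Emits one line per group (`name`, description `"."`, member genes in
#' universe order). Round trip: `read_gmt(write_gmt(a, f))` reproduces the
#' membership matrix restricted to annotated genes.
#'
#' @param a An [annotation_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(a, path) {
  stopifnot(inherits(a, "annotation_matrix"))
  uni <- rownames(a)
  lines <- vapply(seq_len(ncol(a)), function(j) {
    paste(c(colnames(a)[j], ".", uni[a[, j]]), collapse = "\t")
  }, "")
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read GO annotations from a GAF 2.x file
#'
#' Builds one group per GO term from a Gene Association File. Rows whose
#' qualifier contains `NOT` are excluded. With `propagate = TRUE` (requires
#' `obo`), each gene annotated to a term is also made a member of all of the
#' term's `is_a` / `part_of` ancestors (the standard true-path propagation).
#'
#' @param path Path to a GAF 2.x file (`!` comment lines ignored).
#' @param obo Optional path to an OBO 1.2 ontology file; required when
#'   `propagate = TRUE`.
#' @param propagate Propagate annotations to ancestor terms.
#' @param aspect Optional subset of GO aspects to keep, any of
#'   `c("P", "F", "C")`; default keeps all.
#' @param id_column Which GAF column identifies the gene: `"symbol"`
#'   (column 3, default) or `"id"` (column 2).
#' @param universe Optional gene universe (see [read_gmt()]).
#' @return An [annotation_matrix()].
#' @export
read_gaf <- function(path, obo = NULL, propagate = FALSE,
                     aspect = c("P", "F", "C"),
                     id_column = c("symbol", "id"), universe = NULL) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  if (propagate && is.null(obo)) {
    abort("`propagate = TRUE` requires an `obo` file.")
  }
  id_column <- match.arg(id_column)
  aspect <- match.arg(aspect, several.ok = TRUE)
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  if (length(lines) == 0) abort("GAF file contains no annotation rows.")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 9)
  if (length(bad) > 0) {
    abort(sprintf("Malformed GAF line %d: fewer than 9 columns.", bad[1]))
  }
  gene_col <- if (id_column == "symbol") 3L else 2L
  gene <- vapply(fields, `[[`, "", gene_col)
  qualifier <- vapply(fields, `[[`, "", 4L)
  term <- vapply(fields, `[[`, "", 5L)
  asp <- vapply(fields, `[[`, "", 9L)
  keep <- !grepl("(^|\\|)NOT($|\\|)", qualifier) & asp %in% aspect
  gene <- gene[keep]
  term <- term[keep]
  if (length(gene) == 0) abort("No usable GAF rows after filtering.")
  memb <- unique(data.frame(gene = gene, term = term,
                            stringsAsFactors = FALSE))
  if (propagate) {
    anc <- read_obo_ancestors(obo)
    extra <- lapply(seq_len(nrow(memb)), function(i) {
      t <- memb$term[i]
      up <- anc[[t]]
      if (is.null(up)) {
        warn(sprintf("Term %s not found in ontology; kept unpropagated.", t))
        return(NULL)
      }
      if (length(up) == 0) return(NULL)
      data.frame(gene = memb$gene[i], term = up, stringsAsFactors = FALSE)
    })
    memb <- unique(rbind(memb, do.call(rbind, extra)))
  }
  uni <- if (is.null(universe)) sort(unique(memb$gene)) else
    as.character(universe)
  terms <- sort(unique(memb$term))
  m <- matrix(FALSE, length(uni), length(terms), dimnames = list(uni, terms))
  ok <- memb$gene %in% uni
  if (!all(ok)) {
    inform(sprintf(
      "read_gaf: %d annotation row(s) refer to genes outside the universe.",
      sum(!ok)
    ))
  }
  m[cbind(memb$gene[ok], memb$term[ok])] <- TRUE
  annotation_matrix(m)
}

# Parse an OBO 1.2 file into a list term -> character vector of all
# is_a/part_of ancestors (transitive closure, term itself excluded).
read_obo_ancestors <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readr::read_lines(path)
  parents <- list()
  cur <- NULL
  in_term <- FALSE
  for (ln in lines) {
    if (ln == "[Term]") {
      in_term <- TRUE
      cur <- NULL
    } else if (startsWith(ln, "[")) {
      in_term <- FALSE
      cur <- NULL
    } else if (in_term && startsWith(ln, "id: ")) {
      cur <- sub("^id: ", "", ln)
      if (is.null(parents[[cur]])) parents[[cur]] <- character()
    } else if (in_term && !is.null(cur) && startsWith(ln, "is_a: ")) {
      p <- sub("^is_a: *([^ !]+).*$", "\\1", ln)
      parents[[cur]] <- c(parents[[cur]], p)
    } else if (in_term && !is.null(cur) &&
               startsWith(ln, "relationship: part_of ")) {
      p <- sub("^relationship: part_of *([^ !]+).*$", "\\1", ln)
      parents[[cur]] <- c(parents[[cur]], p)
    }
  }
  # transitive closure by repeated expansion (ontologies are DAGs)
  closure <- parents
  repeat {
    changed <- FALSE
    for (t in names(closure)) {
      up <- closure[[t]]
      grand <- unique(unlist(closure[intersect(up, names(closure))]))
      new <- union(up, grand)
      if (length(new) > length(up)) {
        closure[[t]] <- new
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  lapply(closure, function(x) setdiff(unique(x), character(0)))
}
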