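#' Construct a gene set
#'
#' @param name Non-empty set name.
#' @param genes Character vector of gene symbols; upper-case folded and
#'   de-duplicated.
#' @param description Optional free-text description.
#' @return An object of class `GeneSet`.
#' @export
gene_set <- function(name, genes, description = "") {
  name <- as.character(name)
  if (length(name) != 1L || !nzchar(name)) estop("gene set name must be non-empty")
  genes <- unique(fold_id(as.character(genes)))
  genes <- genes[nzchar(genes)]
  if (length(genes) < 1L) estop("gene set '%s' has no genes", name)
  structure(list(name = name, description = as.character(description),
                 genes = genes),
            class = "GeneSet")
}

#' @export
print.GeneSet <- function(x, ...) {
  cat(sprintf("GeneSet '%s': %d genes\n", x$name, length(x$genes)))
  invisible(x)
}

#' Construct a gene-set collection
#'
#' @param sets List of [gene_set()] objects with unique names.
#' @param source Provenance string (file path or fixture id).
#' @return An object of class `GeneSetCollection`.
#' @export
gene_set_collection <- function(sets, source = "") {
  if (!is.list(sets) || !all(vapply(sets, inherits, logical(1L), "GeneSet"))) {
    estop("'sets' must be a list of GeneSet objects")
  }
  nm <- vapply(sets, `[[`, character(1L), "name")
  dup <- duplicated(nm)
  if (any(dup)) estop("duplicate gene set name: '%s'", nm[dup][1L])
  names(sets) <- nm
  structure(list(sets = sets, source = as.character(source)),
            class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat(sprintf("GeneSetCollection: %d sets (source: %s)\n",
              length(x$sets), if (nzchar(x$source)) x$source else "<none>"))
  invisible(x)
}

#' @export
length.GeneSetCollection <- function(x) length(x$sets)

#' Read gene sets in GMT format
#'
#' One set per line, tab-separated: name, description, then gene symbols.
#' Symbols are upper-case folded; empty fields are dropped and within-set
#' duplicates collapsed.
#'
#' @param path Path to the GMT file.
#' @return A [gene_set_collection()] preserving file order.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) estop("GMT file not found: '%s'", path)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  sets <- vector("list", sum(keep))
  j <- 0L
  for (i in seq_along(lines)) {
    if (!keep[i]) next
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      estop("GMT parse error at line %d of '%s': expected >=3 tab-separated fields, got %d",
            i, path, length(fields))
    }
    j <- j + 1L
    sets[[j]] <- gene_set(fields[1L], fields[-(1:2)], description = fields[2L])
  }
  gene_set_collection(sets[seq_len(j)], source = path)
}

#' Write a gene-set collection in GMT format
#'
#' @param collection A [gene_set_collection()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "GeneSetCollection"))
  lines <- vapply(collection$sets, function(s) {
    desc <- if (nzchar(s$description)) s$description else "na"
    paste(c(s$name, desc, s$genes), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Pairwise overlap of gene sets in a collection
#'
#' Computes, for every ordered pair of sets, the intersection size and the
#' Jaccard index. Useful for comparing alternative E/M marker lists, whose
#' published versions overlap surprisingly little.
#'
#' @param collection A [gene_set_collection()] with at least two sets.
#' @return A `data.frame` with columns `set_i`, `set_j`, `intersection`,
#'   `jaccard`; symmetric with unit diagonal.
#' @export
geneset_overlap <- function(collection) {
  stopifnot(inherits(collection, "GeneSetCollection"))
  n <- length(collection$sets)
  if (n < 2L) estop("overlap requires at least two gene sets")
  nm <- names(collection$sets)
  grid <- expand.grid(i = seq_len(n), j = seq_len(n))
  res <- lapply(seq_len(nrow(grid)), function(r) {
    gi <- collection$sets[[grid$i[r]]]$genes
    gj <- collection$sets[[grid$j[r]]]$genes
    inter <- length(intersect(gi, gj))
    un <- length(union(gi, gj))
    data.frame(set_i = nm[grid$i[r]], set_j = nm[grid$j[r]],
               intersection = inter, jaccard = inter / un,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Load the packaged E/M marker gene sets
#'
#' Returns a small curated collection of widely recognized epithelial and
#' mesenchymal marker genes (`E` and `M` sets). This built-in list is a
#' convenience placeholder so the pipeline runs out of the box; for real
#' analyses users should supply their preferred published E/M gene sets as a
#' GMT file.
#'
#' @return A [gene_set_collection()] with sets `E` and `M`.
#' @export
builtin_em_genesets <- function() {
  path <- system.file("extdata", "emt_markers_builtin.gmt", package = "emtax")
  if (!nzchar(path)) estop("packaged gene-set fixture not found")
  read_gmt(path)
}
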