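#' Driver-gene to hallmark map
#'
#' The genome of every simulated melanocyte is a binary vector of
#' `n_genes` genes (default 50) of which seven are melanoma driver genes.
#' Each driver carries a set of hallmark tags that determine how a mutation
#' at that locus changes the cell's action probabilities and antigenicity:
#' `p` (increased proliferation), `q` (increased survival), `r` (genetic
#' instability), `c` (decreased antigenicity, i.e. immune evasion) and
#' `ct` (increased antigenicity). The foundational melanoma mutations
#' BRAF, NRAS and KIT are mutually exclusive: a genome can carry at most
#' one of them.
#'
#' `driver_map()` returns the package default map (BRAF, NRAS, KIT, TERT,
#' CDKN2A, MITF, PTEN at loci 1-7). The `"hot"` variant removes the
#' immune-evasion tag `c` from BRAF, turning the founder clone into a
#' high-antigenicity ("hot") tumor; the default `"cold"` variant keeps it.
#' The hallmark assignments are editable package conventions: ship your own
#' YAML file and load it with [read_driver_map()] to change them.
#'
#' @param variant `"cold"` (BRAF retains immune evasion) or `"hot"`
#'   (immune-evasion tag removed from BRAF).
#' @return A tibble of class `driver_map` with columns `gene`, `locus`, and
#'   `tags` (list column of character tags), plus attributes `n_genes`,
#'   `exclusivity` (gene names), `motility_gene` and `founder_gene`.
#' @examples
#' driver_map()
#' driver_map("hot")
#' @export
driver_map <- function(variant = c("cold", "hot")) {
  variant <- match.arg(variant)
  map <- read_driver_map(system.file("extdata", "driver_map.yaml",
                                     package = "ithsim"))
  if (variant == "hot") {
    i <- which(map$gene == attr(map, "motility_gene"))
    map$tags[[i]] <- setdiff(map$tags[[i]], "c")
  }
  map
}

#' Read or write a driver map as a YAML config
#'
#' @param path File path of a YAML driver-map config with fields `n_genes`,
#'   `drivers` (list of `gene`, `locus`, `tags`), `exclusivity`,
#'   `motility_gene` and `founder_gene`.
#' @return `read_driver_map()` returns a validated `driver_map` tibble;
#'   `write_driver_map()` returns `path` invisibly.
#' @seealso [driver_map()]
#' @export
read_driver_map <- function(path) {
  y <- yaml::read_yaml(path)
  map <- tibble::tibble(
    gene  = purrr::map_chr(y$drivers, "gene"),
    locus = purrr::map_int(y$drivers, ~ as.integer(.x$locus)),
    tags  = purrr::map(y$drivers, ~ as.character(.x$tags))
  )
  attr(map, "n_genes") <- as.integer(y$n_genes %||% 50L)
  attr(map, "exclusivity") <- as.character(y$exclusivity %||% character())
  attr(map, "motility_gene") <- y$motility_gene %||% NA_character_
  attr(map, "founder_gene") <- y$founder_gene %||% map$gene[[1]]
  class(map) <- c("driver_map", class(map))
  validate_driver_map(map)
}

#' @rdname read_driver_map
#' @param map A `driver_map` object.
#' @export
write_driver_map <- function(map, path) {
  map <- validate_driver_map(map)
  y <- list(
    n_genes = attr(map, "n_genes"),
    drivers = purrr::pmap(map, function(gene, locus, tags)
      list(gene = gene, locus = locus, tags = as.list(tags))),
    exclusivity = as.list(attr(map, "exclusivity")),
    motility_gene = attr(map, "motility_gene"),
    founder_gene = attr(map, "founder_gene")
  )
  yaml::write_yaml(y, path)
  invisible(path)
}

valid_tags <- c("p", "q", "r", "c", "ct")

validate_driver_map <- function(map) {
  n_genes <- attr(map, "n_genes")
  if (is.null(n_genes) || n_genes < 1L)
    stop("driver map must carry a positive `n_genes` attribute")
  if (anyDuplicated(map$locus))
    stop("driver loci must be unique")
  if (any(map$locus < 1L | map$locus > n_genes))
    stop("driver loci must lie in 1..n_genes")
  bad <- setdiff(unlist(map$tags), valid_tags)
  if (length(bad))
    stop("unknown hallmark tags: ", paste(bad, collapse = ", "))
  ex <- attr(map, "exclusivity")
  if (!all(ex %in% map$gene))
    stop("exclusivity group names genes absent from the map")
  map
}

# 0-based locus/tag encoding handed to the C++ engine
driver_map_encoding <- function(map) {
  tags <- matrix(0L, nrow = nrow(map), ncol = 5,
                 dimnames = list(map$gene, valid_tags))
  for (i in seq_len(nrow(map)))
    tags[i, map$tags[[i]]] <- 1L
  motil <- attr(map, "motility_gene")
  list(
    driver_idx = as.integer(map$locus - 1L),
    driver_tags = tags,
    excl_idx = as.integer(map$locus[match(attr(map, "exclusivity"), map$gene)] - 1L),
    motility_locus = if (is.na(motil)) -1L else
      as.integer(map$locus[match(motil, map$gene)] - 1L),
    founder_locus = as.integer(map$locus[match(attr(map, "founder_gene"), map$gene)] - 1L),
    n_genes = attr(map, "n_genes")
  )
}
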