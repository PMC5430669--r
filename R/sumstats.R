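# The four Wakeley-Hey polymorphism summary statistics: counts of sites
# with a derived polymorphism private to the west, private to the east,
# shared between the populations, or fixed between them.

WH_CLASSES <- c("private_west", "private_east", "shared", "fixed")

#' Classify one polarised site
#'
#' Given the observed bases in each population and the ancestral base
#' (the outgroup state), assigns the Wakeley-Hey class of the site:
#' polymorphic in the west only -> `private_west` (symmetrically for the
#' east), polymorphic in both -> `shared`, a between-population
#' difference with no within-population variation -> `fixed`.  Sites with
#' more than two states over sample plus ancestral cannot be polarised
#' under infinite sites and return `unpolarizable`; invariant sites (or
#' sites where both populations are fixed for the same base) return
#' `monomorphic`.
#'
#' @param west_alleles,east_alleles Character vectors of bases over
#'   A,C,G,T observed in each population (>= 1 each).
#' @param ancestral Ancestral base.
#' @return One of `private_west`, `private_east`, `shared`, `fixed`,
#'   `monomorphic`, `unpolarizable`.
#' @export
classify_site <- function(west_alleles, east_alleles, ancestral) {
  if (length(west_alleles) < 1 || length(east_alleles) < 1) {
    stop("each population needs at least one sampled allele")
  }
  bases <- c(west_alleles, east_alleles, ancestral)
  if (!all(bases %in% c("A", "C", "G", "T"))) {
    stop("bases must be A, C, G or T")
  }
  if (length(unique(bases)) > 2) return("unpolarizable")
  poly_w <- length(unique(west_alleles)) > 1
  poly_e <- length(unique(east_alleles)) > 1
  if (poly_w && poly_e) return("shared")
  if (poly_w) return("private_west")
  if (poly_e) return("private_east")
  if (west_alleles[1] != east_alleles[1]) return("fixed")
  "monomorphic"
}

#' Per-site Wakeley-Hey classes of one alignment
#'
#' Restricts to sites whose coding classification is
#' `synonymous_variable` (see [classify_synonymous_sites()]), polarises
#' each by the outgroup base, and classifies it with [classify_site()].
#'
#' @param aln A [locus_alignment()] with an outgroup and `frame_offset`
#'   set.
#' @return A tibble with columns `site` and `class` over all alignment
#'   sites; non-synonymous-variable sites carry class `not_considered`.
#' @export
wh_site_classes <- function(aln) {
  if (is.na(aln$outgroup_seq)) stop("outgroup sequence required to polarise sites")
  syn <- classify_synonymous_sites(aln)
  m <- alignment_matrix(aln)
  outg <- strsplit(aln$outgroup_seq, "")[[1]]
  is_west <- aln$alleles$population == "west"
  cls <- rep("not_considered", aln$length)
  for (j in which(syn$class == "synonymous_variable")) {
    col <- m[, j]
    if (!all(c(col, outg[j]) %in% c("A", "C", "G", "T"))) {
      cls[j] <- "unpolarizable"
      next
    }
    cls[j] <- classify_site(col[is_west], col[!is_west], outg[j])
  }
  tibble::tibble(site = syn$site, class = cls)
}

#' The four Wakeley-Hey sums across loci
#'
#' Accepts a list of classified loci -- [locus_alignment()] objects
#' (classified via [wh_site_classes()]), `sim_locus` objects from
#' [drop_mutations()], or per-site class tibbles -- and sums the four
#' components across loci.  Monomorphic and unpolarizable sites
#' contribute nothing.
#'
#' @param dataset A list as described above (a single element is also
#'   accepted).
#' @return A one-row tibble with columns `private_west`, `private_east`,
#'   `shared`, `fixed`, with the per-locus breakdown in attribute
#'   `by_locus`.
#' @export
wakeley_hey <- function(dataset) {
  if (inherits(dataset, c("locus_alignment", "sim_locus")) ||
      is.data.frame(dataset)) {
    dataset <- list(dataset)
  }
  per_locus <- purrr::imap(dataset, function(x, i) {
    classes <- if (inherits(x, "locus_alignment")) wh_site_classes(x)$class
      else x$class
    nm <- if (inherits(x, "locus_alignment")) x$locus_name else as.character(i)
    counts <- vapply(WH_CLASSES, function(k) sum(classes == k), 1L)
    tibble::tibble(locus = nm, !!!as.list(counts))
  })
  by_locus <- dplyr::bind_rows(per_locus)
  total <- dplyr::summarise(by_locus,
                            dplyr::across(dplyr::all_of(WH_CLASSES), sum))
  attr(total, "by_locus") <- by_locus
  total
}

wh_as_vector <- function(stats) {
  if (is.data.frame(stats)) {
    unlist(stats[1, WH_CLASSES])
  } else {
    stopifnot(length(stats) == 4)
    stats <- unlist(stats)
    if (!is.null(names(stats)) && all(WH_CLASSES %in% names(stats))) {
      stats[WH_CLASSES]
    } else {
      setNames(stats, WH_CLASSES)
    }
  }
}
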