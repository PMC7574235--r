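# Gene-family evolution along a species tree: a linear birth-and-death
# process (duplication rate lambda, loss rate mu per lineage per unit
# branch length) generating a gene tree, an exact event log, and leaf
# protein sequences evolved by per-site Poisson substitution.

#' Scenario for a birth-and-death family simulation
#'
#' @param species_tree Rooted binary `ape::phylo` with branch lengths, or a
#'   newick string.
#' @param lambda Duplication (birth) rate per lineage per unit branch length.
#' @param mu Loss (death) rate.
#' @param subst_rate Expected substitutions per residue per unit branch
#'   length for the evolved proteins.
#' @param root_protein Protein at the family root.
#' @param seed RNG seed.
#' @return List of class `family_scenario`.
#' @export
family_scenario <- function(species_tree, lambda = 0.5, mu = 0,
                            subst_rate = 0.05,
                            root_protein = synthetic_seed_protein(),
                            seed = 1L) {
  if (is.character(species_tree)) species_tree <- read_newick(species_tree)
  stopifnot(lambda >= 0, mu >= 0, !is.null(species_tree$edge.length))
  if (!is_binary_tree(species_tree))
    stop("species tree must be binary", call. = FALSE)
  structure(list(species_tree = species_tree, lambda = lambda, mu = mu,
                 subst_rate = subst_rate, root_protein = root_protein,
                 seed = seed),
            class = "family_scenario")
}

evolve_protein <- function(protein, t, rate) {
  if (t <= 0 || rate <= 0) return(protein)
  p <- strsplit(protein, "")[[1L]]
  hit <- which(stats::runif(length(p)) < 1 - exp(-rate * t))
  for (i in hit) p[i] <- sample(setdiff(AA20, p[i]), 1L)
  paste(p, collapse = "")
}

#' Simulate a gene family along a species tree
#'
#' Each gene lineage independently duplicates at rate `lambda` and dies at
#' rate `mu` along every species-tree branch; surviving lineages split at
#' speciations.  The event log records every duplication and loss with its
#' species branch and time; leaf proteins are evolved from the root protein
#' along the realized gene tree.  Gene-tree leaves are named
#' `<species>_g<k>`, encoding the species of origin.
#'
#' @param scenario A [family_scenario()].
#' @return List: `gene_tree` (`ape::phylo`, or `NULL` when fewer than two
#'   genes survive), `leaf_names`, `proteins` (named vector), `events`
#'   (data frame: `event`, `species_branch`, `time`), `extinct` flag.
#' @export
simulate_family <- function(scenario) {
  stopifnot(inherits(scenario, "family_scenario"))
  sp <- scenario$species_tree
  lam <- scenario$lambda; mu <- scenario$mu
  ntip <- length(sp$tip.label)
  root <- ntip + 1L
  kids <- function(v) sp$edge[sp$edge[, 1L] == v, 2L]
  elen <- function(v) sp$edge.length[sp$edge[, 2L] == v]
  node_lab <- function(v) {
    if (v <= ntip) sp$tip.label[v]
    else if (!is.null(sp$node.label) && nzchar(sp$node.label[v - ntip]))
      sp$node.label[v - ntip]
    else paste0("n", v)
  }
  with_seed(scenario$seed, {
    ev <- list()
    counter <- new.env(parent = emptyenv())
    leaf_name <- function(species) {
      k <- (get0(species, envir = counter, ifnotfound = 0L)) + 1L
      assign(species, k, envir = counter)
      paste0(species, "_g", k)
    }
    # returns a node list(name, len, children, protein?) or NULL (extinct)
    at_node <- function(v, protein) {
      if (v <= ntip) {
        nm <- leaf_name(sp$tip.label[v])
        return(list(name = nm, len = 0, children = NULL, protein = protein))
      }
      ch <- kids(v)
      sub <- list()
      for (cv in ch) {
        s <- along_branch(cv, elen(cv), protein)
        if (!is.null(s)) sub[[length(sub) + 1L]] <- s
      }
      if (length(sub) == 0L) return(NULL)
      if (length(sub) == 1L) {   # suppress unary speciation node
        sub[[1L]]$len <- sub[[1L]]$len
        return(sub[[1L]])
      }
      list(name = "", len = 0, children = sub, protein = protein)
    }
    along_branch <- function(v, remaining, protein) {
      consumed <- 0
      repeat {
        rate <- lam + mu
        tev <- if (rate > 0) stats::rexp(1L, rate) else Inf
        if (tev >= remaining) {
          protein <- evolve_protein(protein, remaining, scenario$subst_rate)
          node <- at_node(v, protein)
          if (is.null(node)) return(NULL)
          node$len <- node$len + remaining + consumed
          return(node)
        }
        remaining <- remaining - tev
        consumed <- consumed + tev
        protein <- evolve_protein(protein, tev, scenario$subst_rate)
        if (stats::runif(1L) < lam / rate) {
          ev[[length(ev) + 1L]] <<- data.frame(
            event = "duplication", species_branch = node_lab(v),
            time = consumed, stringsAsFactors = FALSE)
          a <- along_branch(v, remaining, protein)
          b <- along_branch(v, remaining, protein)
          if (is.null(a) && is.null(b)) return(NULL)
          if (is.null(a)) { b$len <- b$len + consumed; return(b) }
          if (is.null(b)) { a$len <- a$len + consumed; return(a) }
          return(list(name = "", len = consumed, children = list(a, b),
                      protein = protein))
        } else {
          ev[[length(ev) + 1L]] <<- data.frame(
            event = "loss", species_branch = node_lab(v),
            time = consumed, stringsAsFactors = FALSE)
          return(NULL)
        }
      }
    }
    tree0 <- at_node(root, scenario$root_protein)
    events <- if (length(ev)) do.call(rbind, ev) else
      data.frame(event = character(), species_branch = character(),
                 time = numeric(), stringsAsFactors = FALSE)
    collect <- function(nd) {
      if (is.null(nd$children)) {
        return(stats::setNames(list(nd$protein), nd$name))
      }
      do.call(c, lapply(nd$children, collect))
    }
    to_newick <- function(nd) {
      if (is.null(nd$children)) return(sprintf("%s:%g", nd$name, nd$len))
      sprintf("(%s):%g", paste(vapply(nd$children, to_newick, character(1)),
                               collapse = ","), nd$len)
    }
    if (is.null(tree0)) {
      return(list(gene_tree = NULL, leaf_names = character(),
                  proteins = character(), events = events, extinct = TRUE))
    }
    prots <- unlist(collect(tree0))
    if (length(prots) < 2L) {
      return(list(gene_tree = NULL, leaf_names = names(prots),
                  proteins = prots, events = events, extinct = FALSE))
    }
    gt <- read_newick(paste0(to_newick(tree0), ";"))
    list(gene_tree = gt, leaf_names = names(prots), proteins = prots,
         events = events, extinct = FALSE)
  })
}
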