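# Readers and writers: FASTA, VCF haplotypes, ARG JSON/GraphML, Newick,
# run-configuration JSON.  All user-facing coordinates are 1-based
# inclusive; internal coordinates are 0-based half-open.

#' Read a FASTA alignment
#'
#' Accepts wrapped or unwrapped FASTA; sequences are uppercased and
#' validated (equal lengths, `A C G T N -` only).
#'
#' @param path FASTA file.
#' @return an [alignment()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dna <- ape::read.FASTA(path)
  if (length(dna) == 0) stop("empty FASTA file: ", path)
  chs <- lapply(as.character(dna), toupper)
  lens <- lengths(chs)
  if (length(unique(lens)) != 1) {
    bad <- names(dna)[which(lens != lens[1])[1]]
    stop(sprintf("ragged alignment: record '%s' has length %d, expected %d",
                 bad, lens[lens != lens[1]][1], lens[1]))
  }
  m <- do.call(rbind, chs)
  m[m == "?"] <- "N"
  alignment(m, names = names(dna))
}

#' Write an alignment as FASTA
#' @param alignment an [alignment()].
#' @param path output file.
#' @param width line width for wrapping.
#' @export
write_fasta <- function(alignment, path, width = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(alignment$matrix))) {
    writeLines(paste0(">", alignment$names[i]), con)
    s <- paste(alignment$matrix[i, ], collapse = "")
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Import phased haplotypes from a VCF
#'
#' Builds one alignment row per haplotype from phased genotypes (`|`
#' separator) or haploid calls.  Two modes:
#' * `variant_only`: columns are the variant sites; the number of
#'   monomorphic sites in the stated region is recorded (composition from
#'   REF-allele frequencies) and folded into the likelihood as invariant
#'   columns, so that `theta` stays interpretable.
#' * `region_fill`: monomorphic columns between variants are filled from
#'   an explicit reference sequence for the region.
#'
#' Indels and records with symbolic alleles are skipped with a warning.
#'
#' @param path VCF file (4.x, plain text or bgzipped).
#' @param samples sample names to import (default: all).
#' @param mode `"variant_only"` or `"region_fill"`.
#' @param region_length total length of the region (required for
#'   `variant_only`'s invariant-site correction; `NULL` disables the
#'   correction).
#' @param ref reference sequence for the region (character scalar,
#'   required for `region_fill`); variant positions are interpreted as
#'   1-based offsets into it.
#' @return an [alignment()] of haplotypes named `<sample>_1`, `<sample>_2`.
#' @export
read_vcf_haplotypes <- function(path, samples = NULL,
                                mode = c("variant_only", "region_fill"),
                                region_length = NULL, ref = NULL) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stop("VCF has no genotype (GT) fields")
  if (is.null(samples)) samples <- colnames(gt)
  miss <- setdiff(samples, colnames(gt))
  if (length(miss) > 0) stop("samples not in VCF: ", paste(miss, collapse = ", "))
  gt <- gt[, samples, drop = FALSE]
  ref_al <- fix[, "REF"]
  alt_al <- fix[, "ALT"]
  pos <- as.integer(fix[, "POS"])
  keep <- rep(TRUE, length(pos))
  allele_lists <- vector("list", length(pos))
  for (i in seq_along(pos)) {
    alleles <- c(ref_al[i], strsplit(alt_al[i], ",", fixed = TRUE)[[1]])
    if (any(nchar(alleles) != 1) || any(!alleles %in% c("A", "C", "G", "T"))) {
      keep[i] <- FALSE
    }
    allele_lists[[i]] <- alleles
  }
  if (any(!keep)) {
    warning(sprintf("skipped %d non-SNP record(s) (indels/symbolic alleles)",
                    sum(!keep)))
  }
  idx <- which(keep)
  if (length(idx) == 0) stop("no usable SNP records in VCF")
  # determine ploidy per sample from the first kept record; build haplotypes
  hap_names <- character(0)
  hap_cols <- list()
  for (s in samples) {
    g1 <- gt[idx[1], s]
    ploidy <- if (grepl("|", g1, fixed = TRUE)) 2L else
      if (grepl("/", g1, fixed = TRUE)) -1L else 1L
    if (ploidy == -1L) {
      stop(sprintf("unphased genotype '%s' for sample %s at position %s",
                   g1, s, pos[idx[1]]))
    }
    haps <- matrix("N", ploidy, length(idx))
    for (k in seq_along(idx)) {
      g <- gt[idx[k], s]
      if (is.na(g)) next
      if (grepl("/", g, fixed = TRUE)) {
        stop(sprintf("unphased genotype '%s' for sample %s at position %s",
                     g, s, pos[idx[k]]))
      }
      parts <- strsplit(g, "|", fixed = TRUE)[[1]]
      if (length(parts) != ploidy) {
        stop(sprintf("inconsistent ploidy for sample %s at position %s",
                     s, pos[idx[k]]))
      }
      al <- allele_lists[[idx[k]]]
      for (h in seq_len(ploidy)) {
        a <- suppressWarnings(as.integer(parts[h]))
        haps[h, k] <- if (is.na(a)) "N" else al[a + 1L]
      }
    }
    if (ploidy == 1L) {
      hap_names <- c(hap_names, s)
      hap_cols[[length(hap_cols) + 1L]] <- haps
    } else {
      hap_names <- c(hap_names, paste0(s, "_", seq_len(ploidy)))
      for (h in seq_len(ploidy)) {
        hap_cols[[length(hap_cols) + 1L]] <- haps[h, , drop = FALSE]
      }
    }
  }
  m <- do.call(rbind, hap_cols)
  if (mode == "region_fill") {
    if (is.null(ref)) stop("region_fill mode requires `ref`")
    refv <- toupper(strsplit(ref, "")[[1]])
    p <- pos[idx] - min(pos[idx]) + 1L
    if (max(p) > length(refv)) stop("`ref` shorter than the variant span")
    full <- matrix(rep(refv, each = nrow(m)), nrow(m), length(refv))
    full[, p] <- m
    out <- alignment(full, names = hap_names)
  } else {
    inv <- c(A = 0, C = 0, G = 0, T = 0)
    if (!is.null(region_length)) {
      n_inv <- region_length - length(idx)
      if (n_inv < 0) stop("region_length smaller than the number of variants")
      reff <- table(factor(ref_al[idx], levels = c("A", "C", "G", "T")))
      inv <- n_inv * as.numeric(reff) / sum(reff)
      names(inv) <- c("A", "C", "G", "T")
    }
    out <- alignment(m, names = hap_names, invariant_counts = inv)
  }
  attr(out, "positions") <- pos[idx]
  out
}

# --------------------------------------------------------- ARG serialization

#' Serialize an ARG to JSON
#'
#' Schema: `n_tips`, `L`, `tip_labels`, and a `nodes` array with `id`,
#' `height`, `kind`, `children`, `parents`, `breakpoint` (1-based node
#' ids; breakpoints as 0-based internal site indices).
#'
#' @param arg an [new_arg()] object.
#' @param path optional output file; when `NULL` the JSON string is
#'   returned.
#' @return the path (invisibly) or a JSON string.
#' @export
write_arg_json <- function(arg, path = NULL) {
  nd <- arg$nodes
  nodes <- lapply(seq_len(nrow(nd)), function(i) {
    x <- list(
      id = i, height = nd$height[i], kind = nd$kind[i],
      children = as.integer(stats::na.omit(c(nd$child1[i], nd$child2[i]))),
      parents = as.integer(stats::na.omit(c(nd$parent1[i], nd$parent2[i])))
    )
    if (!is.na(nd$breakpoint[i])) x$breakpoint <- nd$breakpoint[i]
    x
  })
  obj <- list(n_tips = arg$n_tips, L = arg$L, tip_labels = arg$tip_labels,
              nodes = nodes)
  if (is.null(path)) {
    as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17)))
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
    invisible(path)
  }
}

#' Read an ARG from JSON written by [write_arg_json()]
#' @param path file or JSON string.
#' @return an [new_arg()] object (annotated).
#' @export
read_arg_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  n <- length(obj$nodes)
  nodes <- data.frame(
    height = vapply(obj$nodes, function(x) as.numeric(x$height), numeric(1)),
    kind = vapply(obj$nodes, function(x) x$kind, character(1)),
    child1 = NA_integer_, child2 = NA_integer_,
    parent1 = NA_integer_, parent2 = NA_integer_,
    breakpoint = NA_integer_
  )
  for (i in seq_len(n)) {
    ch <- unlist(obj$nodes[[i]]$children)
    pa <- unlist(obj$nodes[[i]]$parents)
    if (length(ch) >= 1) nodes$child1[i] <- ch[1]
    if (length(ch) >= 2) nodes$child2[i] <- ch[2]
    if (length(pa) >= 1) nodes$parent1[i] <- pa[1]
    if (length(pa) >= 2) nodes$parent2[i] <- pa[2]
    if (!is.null(obj$nodes[[i]]$breakpoint)) {
      nodes$breakpoint[i] <- obj$nodes[[i]]$breakpoint
    }
  }
  arg <- new_arg(nodes, n_tips = obj$n_tips, L = obj$L,
                 tip_labels = unlist(obj$tip_labels))
  annotate_ancestral_material(arg)
}

#' Write an ARG as GraphML (for visualization tools)
#'
#' Node attributes: height, kind, breakpoint; edges run child -> parent.
#'
#' @param arg an [new_arg()] object.
#' @param path output file.
#' @export
write_arg_graphml <- function(arg, path) {
  nd <- arg$nodes
  edges <- NULL
  for (i in seq_len(nrow(nd))) {
    for (p in c(nd$parent1[i], nd$parent2[i])) {
      if (!is.na(p)) edges <- rbind(edges, c(i, p))
    }
  }
  g <- igraph::graph_from_edgelist(edges, directed = TRUE)
  igraph::V(g)$height <- nd$height[seq_len(igraph::vcount(g))]
  igraph::V(g)$kind <- nd$kind[seq_len(igraph::vcount(g))]
  igraph::V(g)$breakpoint <- ifelse(is.na(nd$breakpoint), -1L, nd$breakpoint)
  lab <- rep("", igraph::vcount(g))
  lab[seq_len(arg$n_tips)] <- arg$tip_labels
  igraph::V(g)$label <- lab
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write marginal trees of an ARG as Newick
#'
#' One line per marginal interval:
#' `<start>\t<end>\t<newick>` with 1-based inclusive site coordinates.
#'
#' @param arg an [new_arg()] object.
#' @param path output file.
#' @export
write_marginal_trees <- function(arg, path) {
  mt <- marginal_trees(arg)
  lines <- vapply(mt, function(e) {
    sprintf("%d\t%d\t%s", e$interval[1] + 1L, e$interval[2],
            marginal_tree_newick(e$tree))
  }, character(1))
  writeLines(c("start\tend\tnewick", lines), path)
  invisible(path)
}

#' Write a breakpoint table (TSV: site, height, class), 1-based sites
#' @param arg an annotated ARG.
#' @param path output file.
#' @export
write_breakpoints <- function(arg, path) {
  bp <- enumerate_breakpoints(arg)
  bp$site <- bp$site + 1L
  utils::write.table(bp[, c("site", "height", "class")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the TMRCA profile of one ARG (TSV), 1-based inclusive intervals
#' @param arg an ARG.
#' @param path output file.
#' @export
write_tmrca_profile <- function(arg, path) {
  prof <- tmrca_profile_of_arg(arg)
  out <- data.frame(start = prof$start + 1L, end = prof$end, tmrca = prof$tmrca)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# --------------------------------------------------------------- run config

#' Write a run configuration (with model settings) as JSON
#' @param config a [run_config()].
#' @param pop,rec,model model components.
#' @param path output file.
#' @export
write_run_config <- function(config, pop, rec, model, path) {
  obj <- list(
    chain_length = config$chain_length,
    sample_interval = config$sample_interval,
    arg_sample_interval = config$arg_sample_interval,
    burnin_fraction = config$burnin_fraction,
    n_chains = config$n_chains,
    temp_lambda = config$temp_lambda,
    swap_interval = config$swap_interval,
    tune = config$tune,
    audit_interval = config$audit_interval,
    seed = config$seed,
    priors = unclass(config$priors),
    theta = pop$theta0, growth = pop$growth, rho = rec$rho,
    model = list(
      family = model$family, freqs = as.numeric(unclass(model$freqs)),
      kappa = model$kappa, alpha_R = model$alpha_R, alpha_Y = model$alpha_Y
    )
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a run configuration written by [write_run_config()]
#' @param path JSON file.
#' @return list with `config`, `pop`, `rec`, `model`.
#' @export
read_run_config <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  priors <- prior_spec(
    theta = as.list(obj$priors$theta), rho = as.list(obj$priors$rho),
    sub = as.list(obj$priors$sub)
  )
  config <- run_config(
    chain_length = obj$chain_length, sample_interval = obj$sample_interval,
    arg_sample_interval = obj$arg_sample_interval,
    burnin_fraction = obj$burnin_fraction, n_chains = obj$n_chains,
    temp_lambda = obj$temp_lambda, swap_interval = obj$swap_interval,
    priors = priors, tune = obj$tune, audit_interval = obj$audit_interval,
    seed = obj$seed
  )
  model <- if (obj$model$family == "F84") {
    substitution_model("F84", base_frequencies(obj$model$freqs),
                       kappa = obj$model$kappa)
  } else {
    substitution_model("TN93", base_frequencies(obj$model$freqs),
                       alpha_R = obj$model$alpha_R, alpha_Y = obj$model$alpha_Y)
  }
  list(
    config = config,
    pop = population_model(obj$theta, obj$growth),
    rec = recombination_model(obj$rho),
    model = model
  )
}
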