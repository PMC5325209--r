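# Model-based term-set analysis.
#
# Generative model: each term is active (1) or inactive (0) with prior
# probability p; an item's hidden state is the OR of its active annotating
# terms; the observed study set flips hidden-off items on with
# false-positive rate alpha and hidden-on items off with false-negative
# rate beta.  Inference targets the marginal posterior activation
# probability of each term, with alpha, beta and p marginalized over
# discrete grids (uniform grid priors).  Exact enumeration over all term
# states serves as the oracle for the Metropolis sampler.

#' Build a term-set analysis model
#'
#' @param annotations data.frame with columns `term` and `item`
#'   (pre-propagated term-to-item annotations; a third `evidence` column
#'   is carried along if present).
#' @param items Character universe of quantifiable items; defaults to the
#'   items appearing in `annotations`.
#' @param study_set Character vector of items observed as regulated; must
#'   be a subset of `items`.
#' @param alpha_grid,beta_grid Discrete supports for the false-positive
#'   and false-negative rates (defaults: 10 points spanning 0.01-0.3).
#' @param p_grid Support for the prior activation probability (default:
#'   10 points from `1/n_terms` to 0.3).
#' @return A list of class `GsaModel`.
#' @export
gsa_model <- function(annotations, items = NULL, study_set,
                      alpha_grid = seq(0.01, 0.3, length.out = 10),
                      beta_grid = seq(0.01, 0.3, length.out = 10),
                      p_grid = NULL) {
  stopifnot(all(c("term", "item") %in% names(annotations)))
  if (is.null(items)) items <- sort(unique(annotations$item))
  if (!all(study_set %in% items))
    stop("study_set must be a subset of the item universe")
  if (!all(annotations$item %in% items))
    stop("annotations reference items outside the universe")
  terms <- sort(unique(annotations$term))
  term_items <- lapply(terms, function(t)
    match(unique(annotations$item[annotations$term == t]), items))
  if (any(lengths(term_items) == 0L))
    stop("every term must annotate >= 1 item")
  if (is.null(p_grid))
    p_grid <- seq(1 / length(terms), 0.3, length.out = 10)
  stopifnot(all(alpha_grid > 0 & alpha_grid < 1),
            all(beta_grid > 0 & beta_grid < 1),
            all(p_grid > 0 & p_grid < 1))
  structure(list(terms = terms,
                 term_items = term_items,
                 items = items,
                 obs = items %in% study_set,
                 study_set = study_set,
                 alpha_grid = alpha_grid,
                 beta_grid = beta_grid,
                 p_grid = p_grid),
            class = "GsaModel")
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Marginal (over the grids) log-likelihood factors given the four
# observation counts and the number of active terms.
gsa_state_logweight <- function(n01, n00, n10, n11, t1, model) {
  la <- log_sum_exp(n01 * log(model$alpha_grid) +
                    n00 * log1p(-model$alpha_grid))
  lb <- log_sum_exp(n10 * log(model$beta_grid) +
                    n11 * log1p(-model$beta_grid))
  lp <- log_sum_exp(t1 * log(model$p_grid) +
                    (length(model$terms) - t1) * log1p(-model$p_grid))
  la + lb + lp
}

gsa_counts <- function(model, active_idx) {
  hidden <- rep(FALSE, length(model$items))
  for (t in active_idx) hidden[model$term_items[[t]]] <- TRUE
  n11 <- sum(hidden & model$obs)
  n10 <- sum(hidden & !model$obs)
  n01 <- sum(!hidden & model$obs)
  n00 <- sum(!hidden & !model$obs)
  c(n01 = n01, n00 = n00, n10 = n10, n11 = n11)
}

#' Exact marginal posteriors by state enumeration
#'
#' Sums the joint over all `2^n_terms` activation vectors and all grid
#' values; exact, but limited to small models. Serves as the oracle for
#' [mgsa_mcmc()].
#'
#' @param model A [gsa_model()].
#' @param max_terms Enumeration guard (default 15).
#' @return data.frame of class `GsaResult`: `term`, `posterior`,
#'   `run_sd` (0: exact), with attribute `method = "enumeration"`.
#' @export
mgsa_enumerate <- function(model, max_terms = 15L) {
  nt <- length(model$terms)
  if (nt > max_terms)
    stop("too many terms for enumeration; use mgsa_mcmc()")
  n_states <- 2^nt
  logw <- numeric(n_states)
  state_has <- matrix(FALSE, n_states, nt)
  for (s in seq_len(n_states) - 1L) {
    act <- which(bitwAnd(s, bitwShiftL(1L, seq_len(nt) - 1L)) != 0L)
    state_has[s + 1L, act] <- TRUE
    cn <- gsa_counts(model, act)
    logw[s + 1L] <- gsa_state_logweight(cn["n01"], cn["n00"], cn["n10"],
                                        cn["n11"], length(act), model)
  }
  w <- exp(logw - log_sum_exp(logw))
  post <- as.numeric(crossprod(state_has, w))
  structure(data.frame(term = model$terms, posterior = post,
                       run_sd = 0, stringsAsFactors = FALSE),
            method = "enumeration", class = c("GsaResult", "data.frame"))
}

mgsa_one_chain <- function(model, n_steps, seed, burn_frac = 0.2,
                           toggle_prob = 0.75) {
  nt <- length(model$terms)
  n_items <- length(model$items)
  obs <- model$obs
  n_obs <- sum(obs)
  la_grid <- model$alpha_grid; lb_grid <- model$beta_grid
  lp_grid <- model$p_grid
  with_seed(seed, {
    state <- rep(FALSE, nt)
    cnt <- integer(n_items)
    h1o <- 0L; h1u <- 0L   # hidden-on items, observed / unobserved
    ia <- sample.int(length(la_grid), 1L)
    ib <- sample.int(length(lb_grid), 1L)
    ip <- sample.int(length(lp_grid), 1L)
    loglik <- function(h1o, h1u, t1, ia, ib, ip) {
      a <- la_grid[ia]; b <- lb_grid[ib]; p <- lp_grid[ip]
      (n_obs - h1o) * log(a) + (n_items - n_obs - h1u) * log1p(-a) +
        h1u * log(b) + h1o * log1p(-b) +
        t1 * log(p) + (nt - t1) * log1p(-p)
    }
    t1 <- 0L
    cur <- loglik(h1o, h1u, t1, ia, ib, ip)
    burn <- floor(burn_frac * n_steps)
    acc <- numeric(nt)
    n_kept <- 0L
    u_all <- NULL  # draw per-step uniforms lazily in blocks
    for (step in seq_len(n_steps)) {
      if (stats::runif(1) < toggle_prob) {
        t <- sample.int(nt, 1L)
        idx <- model$term_items[[t]]
        if (state[t]) {
          turned <- idx[cnt[idx] == 1L]
          d_on <- -1L
        } else {
          turned <- idx[cnt[idx] == 0L]
          d_on <- 1L
        }
        d_h1o <- d_on * sum(obs[turned])
        d_h1u <- d_on * (length(turned) - sum(obs[turned]))
        prop <- loglik(h1o + d_h1o, h1u + d_h1u, t1 + d_on, ia, ib, ip)
        if (log(stats::runif(1)) < prop - cur) {
          state[t] <- !state[t]
          cnt[idx] <- cnt[idx] + d_on
          h1o <- h1o + d_h1o; h1u <- h1u + d_h1u; t1 <- t1 + d_on
          cur <- prop
        }
      } else {
        which_par <- sample.int(3L, 1L)
        ja <- ia; jb <- ib; jp <- ip
        if (which_par == 1L) ja <- sample.int(length(la_grid), 1L)
        else if (which_par == 2L) jb <- sample.int(length(lb_grid), 1L)
        else jp <- sample.int(length(lp_grid), 1L)
        prop <- loglik(h1o, h1u, t1, ja, jb, jp)
        if (log(stats::runif(1)) < prop - cur) {
          ia <- ja; ib <- jb; ip <- jp
          cur <- prop
        }
      }
      if (step > burn) {
        acc <- acc + state
        n_kept <- n_kept + 1L
      }
    }
    acc / n_kept
  })
}

#' Marginal posteriors by Metropolis MCMC
#'
#' Runs `n_runs` independent Metropolis chains over the joint state
#' (term activations, alpha, beta, p on their grids). Proposals toggle a
#' uniformly chosen term or resample one grid parameter. Per-term
#' posteriors are activation frequencies after discarding 20% burn-in,
#' averaged over runs; the SD across runs quantifies Monte Carlo error.
#'
#' @param model A [gsa_model()].
#' @param n_runs Number of independent chains (default 20).
#' @param n_steps Iterations per chain (default 1e6).
#' @param seed Integer seed; chain r uses `seed + r - 1`.
#' @param burn_frac Burn-in fraction (default 0.2).
#' @return data.frame of class `GsaResult`: `term`, `posterior`
#'   (mean over runs), `run_sd`; attributes record the settings. A
#'   warning flags terms whose across-run SD exceeds 0.2 (non-mixing).
#' @export
mgsa_mcmc <- function(model, n_runs = 20L, n_steps = 1e6, seed = 1L,
                      burn_frac = 0.2) {
  chains <- vapply(seq_len(n_runs), function(r)
    mgsa_one_chain(model, n_steps = n_steps, seed = seed + r - 1L,
                   burn_frac = burn_frac),
    numeric(length(model$terms)))
  chains <- matrix(chains, nrow = length(model$terms))
  post <- rowMeans(chains)
  rsd <- apply(chains, 1, stats::sd)
  if (any(rsd > 0.2, na.rm = TRUE))
    warning("MCMC may not have mixed: across-run posterior SD > 0.2 for ",
            sum(rsd > 0.2), " term(s)")
  structure(data.frame(term = model$terms, posterior = post,
                       run_sd = rsd, stringsAsFactors = FALSE),
            method = "mcmc", n_runs = n_runs, n_steps = n_steps,
            seed = seed, class = c("GsaResult", "data.frame"))
}

#' Terms inferred as perturbed
#'
#' @param result A `GsaResult`.
#' @param threshold Posterior cutoff (default 0.5; strictly greater).
#' @return The qualifying rows sorted by decreasing posterior.
#' @export
perturbed_terms <- function(result, threshold = 0.5) {
  out <- result[!is.na(result$posterior) & result$posterior > threshold, ,
                drop = FALSE]
  out[order(-out$posterior), , drop = FALSE]
}

#' Read a minimal GAF-like annotation table
#'
#' Two tab-separated columns `term`, `item`, optional third column
#' `evidence`; lines starting with `!` or `#` are skipped.
#'
#' @param path File path.
#' @return data.frame with columns `term`, `item` and possibly
#'   `evidence`.
#' @export
read_annotations <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!grepl("^[!#]", lines) & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield < 2L)) stop("annotation lines need >= 2 tab-separated fields")
  out <- data.frame(term = vapply(parts, `[`, "", 1L),
                    item = vapply(parts, `[`, "", 2L),
                    stringsAsFactors = FALSE)
  if (all(nfield >= 3L))
    out$evidence <- vapply(parts, `[`, "", 3L)
  if (out$term[1] == "term" && out$item[1] == "item")
    out <- out[-1L, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export a protein-term association network
#'
#' Builds the bipartite edge list linking study-set proteins to their
#' annotated terms, optionally labeled with evidence codes, and writes it
#' as TSV and (optionally) GraphML.
#'
#' @param study_set Character vector of proteins.
#' @param annotations data.frame `term`, `item` (+ optional `evidence`).
#' @param tsv_path,graphml_path Optional output paths.
#' @return data.frame of edges (`protein`, `term`, `evidence`); proteins
#'   absent from the annotations are returned in attribute `"isolated"`
#'   with a warning.
#' @export
export_association_network <- function(study_set, annotations,
                                       tsv_path = NULL,
                                       graphml_path = NULL) {
  keep <- annotations$item %in% study_set
  edges <- data.frame(protein = annotations$item[keep],
                      term = annotations$term[keep],
                      evidence = if ("evidence" %in% names(annotations))
                        annotations$evidence[keep] else NA_character_,
                      stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  isolated <- setdiff(study_set, edges$protein)
  if (length(isolated) > 0L)
    warning(length(isolated), " study-set protein(s) have no annotation")
  attr(edges, "isolated") <- isolated
  if (!is.null(tsv_path))
    utils::write.table(edges, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  if (!is.null(graphml_path)) {
    nodes <- unique(c(edges$protein, edges$term, isolated))
    is_term <- nodes %in% edges$term
    xml <- c('<?xml version="1.0" encoding="UTF-8"?>',
             '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
             '<key id="kind" for="node" attr.name="kind" attr.type="string"/>',
             '<key id="evidence" for="edge" attr.name="evidence" attr.type="string"/>',
             '<graph edgedefault="undirected">',
             sprintf('<node id="%s"><data key="kind">%s</data></node>',
                     nodes, ifelse(is_term, "term", "protein")),
             sprintf('<edge source="%s" target="%s"><data key="evidence">%s</data></edge>',
                     edges$protein, edges$term,
                     ifelse(is.na(edges$evidence), "", edges$evidence)),
             '</graph>', '</graphml>')
    writeLines(xml, graphml_path, useBytes = TRUE)
  }
  edges
}
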