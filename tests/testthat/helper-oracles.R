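# Independent oracles used across the suite. These deliberately avoid the
# package's own traversal / fitting code paths.

# Member tips of every internal node, found by walking each tip's ancestor
# path up the edge matrix (independent of the package's postorder
# accumulation).
oracle_clade_members <- function(tree) {
  ntip <- length(tree$tip.label)
  parent_of <- integer(ntip + tree$Nnode)
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  members <- vector("list", tree$Nnode)
  for (tip in seq_len(ntip)) {
    node <- tip
    while (parent_of[node] != 0) {
      node <- parent_of[node]
      k <- node - ntip
      members[[k]] <- c(members[[k]], tree$tip.label[tip])
    }
  }
  lapply(members, sort)
}

# NB log-likelihood evaluated directly (for the brute-force optimizer).
nb_loglik_direct <- function(par, y, X) {
  p <- ncol(X)
  eta <- drop(X %*% par[1:p])
  mu <- exp(pmin(pmax(eta, -40), 40))
  theta <- exp(par[p + 1])
  sum(dnbinom(y, size = theta, mu = mu, log = TRUE))
}

# Independent direct numerical maximization of the NB log-likelihood
# (Nelder-Mead then BFGS polish), returning (beta, theta).
oracle_nb_direct <- function(y, X) {
  p <- ncol(X)
  start <- c(qr.solve(X, log(pmax(y, 0.5))), 0)
  f <- function(par) -nb_loglik_direct(par, y, X)
  o1 <- optim(start, f, method = "Nelder-Mead",
              control = list(maxit = 5000, reltol = 1e-13))
  o2 <- optim(o1$par, f, method = "BFGS",
              control = list(maxit = 500, reltol = 1e-14))
  best <- if (o2$value <= o1$value) o2 else o1
  list(beta = best$par[1:p], theta = exp(best$par[p + 1]),
       loglik = -best$value)
}

# Random count table over given feature names.
random_table <- function(n_samples, features, lambda = 20, p_zero = 0.3,
                         prefix = "S") {
  counts <- matrix(rpois(n_samples * length(features), lambda) *
                     rbinom(n_samples * length(features), 1, 1 - p_zero),
                   nrow = n_samples,
                   dimnames = list(paste0(prefix, seq_len(n_samples)),
                                   features))
  counts
}

# Minimal metadata for hand-built battery fixtures: n_hosts hosts per
# age/diet cell of one study, two timepoints.
toy_metadata <- function(hosts) {
  do.call(rbind, lapply(c("wk0", "wk6"), function(tp) {
    data.frame(sample_id = paste(hosts$host_id, tp, sep = "_"),
               host_id = hosts$host_id, age = hosts$age, diet = hosts$diet,
               study = hosts$study, timepoint = tp,
               il6 = if (tp == "wk6") hosts$il6 else NA_real_,
               stringsAsFactors = FALSE)
  }))
}

# Wrap a samples x clades matrix as a minimal clade_matrix for the battery
# drivers (tree/members only needed for recovery scoring).
toy_clade_matrix <- function(abund) {
  structure(list(abundance = abund,
                 clades = data.frame(clade_id = colnames(abund),
                                     node = seq_len(ncol(abund)),
                                     n_tips = 1L),
                 members = setNames(as.list(colnames(abund)), colnames(abund)),
                 tree = NULL),
            class = "clade_matrix")
}
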