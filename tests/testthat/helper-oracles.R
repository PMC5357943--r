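# Independent brute-force oracles. These deliberately avoid the package's
# code paths (and igraph where the package uses igraph): statistics are
# recomputed by direct enumeration over an edge list.

# --- cartography -----------------------------------------------------------

# edges: data.frame(a, b, w) of node names and signed weights;
# membership: named integer vector. Returns per-node statistics computed by
# looping over edges, with sample-sd z conventions matching the package's
# documented choice.
oracle_cartography <- function(nodes, edges, membership) {
  ncl <- max(membership)
  k <- setNames(integer(length(nodes)), nodes)
  ks <- matrix(0L, length(nodes), ncl, dimnames = list(nodes, NULL))
  wsum <- setNames(numeric(length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    a <- edges$a[i]; b <- edges$b[i]; w <- edges$w[i]
    k[a] <- k[a] + 1L; k[b] <- k[b] + 1L
    ks[a, membership[b]] <- ks[a, membership[b]] + 1L
    ks[b, membership[a]] <- ks[b, membership[a]] + 1L
    wsum[a] <- wsum[a] + w; wsum[b] <- wsum[b] + w
  }
  k_in <- ks[cbind(seq_along(nodes), membership[nodes])]
  P <- ifelse(k > 0, 1 - rowSums((ks / pmax(k, 1))^2), NA_real_)
  K_pi <- ifelse(k > 0, 1 - (k_in / pmax(k, 1))^2, NA_real_)
  z <- z_g <- setNames(numeric(length(nodes)), nodes)
  for (cl in unique(membership[nodes])) {
    in_cl <- nodes[membership[nodes] == cl]
    mu_in <- mean(k_in[match(in_cl, nodes)]); sd_in <- sd(k_in[match(in_cl, nodes)])
    mu_tot <- mean(k[in_cl]); sd_tot <- sd(k[in_cl])
    for (nd in in_cl) {
      kin_nd <- k_in[match(nd, nodes)]
      z[nd] <- if (is.na(sd_in) || sd_in == 0) 0 else (kin_nd - mu_in) / sd_in
      z_g[nd] <- if (is.na(sd_tot) || sd_tot == 0) 0 else (kin_nd - mu_tot) / sd_tot
    }
  }
  apcc <- ifelse(k > 0, wsum / pmax(k, 1), NA_real_)
  list(k = k, k_in = setNames(k_in, nodes), k_s = ks, P = setNames(P, nodes),
       K_pi = setNames(K_pi, nodes), z = z, z_g = z_g, apcc = apcc)
}

# --- shortest paths --------------------------------------------------------

# plain BFS over an adjacency list; returns the mean shortest path over
# connected unordered pairs, NA if none.
oracle_asp <- function(nodes, edges) {
  adj <- setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    adj[[edges$a[i]]] <- c(adj[[edges$a[i]]], edges$b[i])
    adj[[edges$b[i]]] <- c(adj[[edges$b[i]]], edges$a[i])
  }
  total <- 0; npairs <- 0L
  for (src_i in seq_along(nodes)[-length(nodes)]) {
    src <- nodes[src_i]
    dist <- setNames(rep(NA_integer_, length(nodes)), nodes)
    dist[src] <- 0L
    queue <- src
    while (length(queue)) {
      cur <- queue[1L]; queue <- queue[-1L]
      for (nb in adj[[cur]]) if (is.na(dist[nb])) {
        dist[nb] <- dist[cur] + 1L
        queue <- c(queue, nb)
      }
    }
    later <- nodes[(src_i + 1L):length(nodes)]
    reach <- later[!is.na(dist[later])]
    total <- total + sum(dist[reach]); npairs <- npairs + length(reach)
  }
  if (npairs == 0L) NA_real_ else total / npairs
}

# --- random fixtures -------------------------------------------------------

# Erdos-Renyi-style weighted graph as edge list + igraph twin built through
# the package's own constructor path (adjacency of signed weights).
random_weighted_graph <- function(n, p_edge, seed) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n))
  corr <- diag(n)
  dimnames(corr) <- list(nodes, nodes)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (runif(1) < p_edge) {
      w <- sample(c(-1, 1), 1L) * runif(1, 0.6, 1)
      corr[i, j] <- corr[j, i] <- w
    }
  }
  g <- build_graph(corr, 0.5)
  el <- igraph::as_data_frame(g, what = "edges")
  edges <- data.frame(a = el$from, b = el$to, w = el$weight,
                      stringsAsFactors = FALSE)
  list(nodes = nodes, edges = edges, g = g)
}

random_membership <- function(nodes, ncl, seed) {
  set.seed(seed)
  repeat {
    m <- setNames(sample.int(ncl, length(nodes), replace = TRUE), nodes)
    if (length(unique(m)) == ncl) return(m)
  }
}

# --- survival --------------------------------------------------------------

# unweighted two-group log-rank chi-square computed from first principles
# (observed vs expected events at each distinct event time).
oracle_logrank_chisq <- function(time, event, grp) {
  ev_times <- sort(unique(time[event == 1]))
  O_minus_E <- 0; V <- 0
  for (t in ev_times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & grp == 1L)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & grp == 1L)
    O_minus_E <- O_minus_E + (d1 - d * n1 / n)
    if (n > 1L) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1L)
  }
  if (V == 0) 0 else O_minus_E^2 / V
}

# product-limit survival computed by hand from (time, event)
oracle_km <- function(time, event) {
  ev_times <- sort(unique(time[event == 1]))
  surv <- numeric(length(ev_times))
  s <- 1
  for (i in seq_along(ev_times)) {
    t <- ev_times[i]
    n_i <- sum(time >= t)
    d_i <- sum(time == t & event == 1)
    s <- s * (1 - d_i / n_i)
    surv[i] <- s
  }
  data.frame(time = ev_times, surv = surv)
}

# --- enrichment ------------------------------------------------------------

# upper-tail hypergeometric probability by direct summation of choose()
# products (log scale for stability).
oracle_hyper_tail <- function(a, K, M, n) {
  if (a <= 0) return(1)
  upper <- min(K, n)
  if (a > upper) return(0)
  j <- a:upper
  terms <- lchoose(K, j) + lchoose(M, n - j) - lchoose(K + M, n)
  sum(exp(terms))
}
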