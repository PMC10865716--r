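#' Group-by-individual matrix
#'
#' Binary events x individuals membership matrix: entry `(e, m)` is 1 when
#' mouse `m` took part in association event `e`. Solitary bouts never form
#' events and so contribute no rows; members absent from `nodes` (e.g.
#' censored that day) are dropped.
#'
#' @param events Event tibble from [association_events()] (typically one
#'   day's events).
#' @param nodes Character vector of mouse ids forming the network's node
#'   set.
#' @return Integer matrix with `length(nodes)` columns (possibly 0 rows).
#' @export
gbi_matrix <- function(events, nodes) {
  nodes <- as.character(nodes)
  g <- matrix(0L, nrow = nrow(events), ncol = length(nodes),
              dimnames = list(NULL, nodes))
  if (nrow(events) > 0L) {
    for (e in seq_len(nrow(events))) {
      mem <- intersect(events$members[[e]], nodes)
      g[e, mem] <- 1L
    }
  }
  g
}

#' Simple Ratio Index
#'
#' For a dyad, `x / (x + y_a + y_b)` where `x` counts events containing
#' both individuals and `y_a`, `y_b` count events containing exactly one:
#' 0 means the pair never shared an event, 1 means they shared every event
#' either attended. Pairs never seen in any event score 0.
#'
#' @param gbi Binary group-by-individual matrix.
#' @return For `sri_matrix()`, the symmetric named SRI matrix with zero
#'   diagonal; for `sri()`, a single index.
#' @export
sri_matrix <- function(gbi) {
  x <- crossprod(gbi)          # co-attendance counts
  a <- diag(x)                 # per-individual event counts
  denom <- outer(a, a, "+") - x
  s <- ifelse(denom > 0, x / denom, 0)
  diag(s) <- 0
  s
}

#' @rdname sri_matrix
#' @param a,b Mouse ids (columns of `gbi`).
#' @export
sri <- function(gbi, a, b) {
  sri_matrix(gbi)[a, b]
}

graph_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] == 0L) {
      cur <- cur + 1L
      queue <- s
      comp[s] <- cur
      while (length(queue) > 0L) {
        v <- queue[1L]
        queue <- queue[-1L]
        nb <- which(adj[v, ] > 0 & comp == 0L)
        comp[nb] <- cur
        queue <- c(queue, nb)
      }
    }
  }
  comp
}

page_rank_weighted <- function(adj, damping = 0.85, tol = 1e-12,
                               max_iter = 2000L) {
  n <- nrow(adj)
  if (n == 0L) return(numeric(0))
  strength <- rowSums(adj)
  dangling <- strength == 0
  P <- adj
  P[!dangling, ] <- adj[!dangling, , drop = FALSE] / strength[!dangling]
  v <- rep(1 / n, n)
  for (i in seq_len(max_iter)) {
    v_new <- (1 - damping) / n +
      damping * (as.vector(crossprod(P, v)) + sum(v[dangling]) / n)
    if (sum(abs(v_new - v)) < tol) {
      v <- v_new
      break
    }
    v <- v_new
  }
  setNames(v, rownames(adj))
}

#' Build a weighted daily social network
#'
#' Constructs the SRI-weighted undirected graph over `nodes` and computes
#' the standard descriptors: connected components over SRI > 0 edges
#' (isolated nodes count as their own components), edge density (observed
#' edges over `n(n-1)/2`), binary degree centrality (neighbors over
#' `n - 1`), node strength (sum of incident SRI weights) and weighted
#' page rank (damping 0.85, transition probability proportional to edge
#' weight).
#'
#' @param gbi Binary group-by-individual matrix (columns = nodes).
#' @param day Optional day label carried on the result.
#' @param damping Page rank damping factor (default 0.85).
#' @return An object of class `rfid_network`: list with `day`, `nodes`,
#'   `adjacency`, `n_components`, `edge_density`, and a `node_metrics`
#'   tibble.
#' @export
build_daily_network <- function(gbi, day = NA_integer_, damping = 0.85) {
  nodes <- colnames(gbi)
  adj <- sri_matrix(gbi)
  n <- length(nodes)
  binary <- adj > 0
  n_edges <- sum(binary[upper.tri(binary)])
  comp <- graph_components(adj)
  node_metrics <- tibble::tibble(
    mouse_id = nodes,
    degree_centrality = if (n > 1) unname(rowSums(binary)) / (n - 1) else NA_real_,
    strength = unname(rowSums(adj)),
    page_rank = as.numeric(page_rank_weighted(adj, damping)),
    component = comp
  )
  structure(list(
    day = day,
    nodes = nodes,
    adjacency = adj,
    n_components = if (n == 0L) 0L else max(comp),
    edge_density = if (n > 1) n_edges / (n * (n - 1) / 2) else NA_real_,
    n_edges = n_edges,
    node_metrics = node_metrics
  ), class = "rfid_network")
}

#' @export
print.rfid_network <- function(x, ...) {
  cat("<rfid_network> day ", x$day, ": ", length(x$nodes), " nodes, ",
      x$n_edges, " edges, ", x$n_components, " components, density ",
      signif(x$edge_density, 3), "\n", sep = "")
  invisible(x)
}

#' @method tidy rfid_network
#' @export
tidy.rfid_network <- function(x, ...) {
  adj <- x$adjacency
  idx <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
  tibble::tibble(
    day = x$day,
    mouse_a = rownames(adj)[idx[, 1]],
    mouse_b = colnames(adj)[idx[, 2]],
    sri = adj[idx]
  )
}

#' @method glance rfid_network
#' @export
glance.rfid_network <- function(x, ...) {
  tibble::tibble(day = x$day, n_nodes = length(x$nodes),
                 n_edges = x$n_edges, n_components = x$n_components,
                 edge_density = x$edge_density)
}

#' Daily social networks across a trial
#'
#' One SRI-weighted network per trial day, built from that day's
#' association events over the mice observable (uncensored) that day.
#'
#' @param events Event tibble from [association_events()].
#' @param mice Metadata tibble.
#' @param config An [enclosure_config()].
#' @param days Day indices (default all trial days).
#' @return Named list of `rfid_network` objects (one per day).
#' @export
daily_networks <- function(events, mice, config = enclosure_config(),
                           days = seq_len(config$trial_days)) {
  nets <- purrr::map(days, function(d) {
    nodes <- mice_alive_on(mice, d)
    build_daily_network(gbi_matrix(events[events$day == d, ], nodes),
                        day = d)
  })
  setNames(nets, paste0("day", days))
}

#' Tabulate network metrics across days
#'
#' @param networks List of `rfid_network` objects from [daily_networks()].
#' @return List of two tibbles: `graph` (one row per day) and `nodes`
#'   (one row per mouse-day).
#' @export
network_metrics <- function(networks) {
  list(
    graph = purrr::map_dfr(networks, glance),
    nodes = purrr::map_dfr(networks,
                           ~ dplyr::mutate(.x$node_metrics, day = .x$day,
                                           .before = 1))
  )
}

#' Cumulative fraction of available partners ever met
#'
#' For each mouse and day D, the fraction of available partners (mice
#' observable on day D, excluding the focal mouse) with whom the focal
#' mouse has shared at least one association event on any day up to D.
#' Non-decreasing in D while the denominator is constant.
#'
#' @param events Event tibble from [association_events()].
#' @param mice Metadata tibble.
#' @param config An [enclosure_config()].
#' @return Tibble: `mouse_id`, `day`, `n_met`, `n_available`,
#'   `fraction_met`.
#' @export
cumulative_partners <- function(events, mice,
                                config = enclosure_config()) {
  days <- seq_len(config$trial_days)
  ids <- mice$mouse_id
  met <- setNames(vector("list", length(ids)), ids)
  for (m in ids) met[[m]] <- character(0)
  rows <- vector("list", length(days))
  for (d in days) {
    ev <- events[events$day == d, ]
    if (nrow(ev) > 0L) {
      for (e in seq_len(nrow(ev))) {
        mem <- ev$members[[e]]
        for (m in mem) met[[m]] <- union(met[[m]], setdiff(mem, m))
      }
    }
    alive <- mice_alive_on(mice, d)
    rows[[d]] <- tibble::tibble(
      mouse_id = alive,
      day = d,
      n_met = vapply(alive, function(m)
        length(intersect(met[[m]], alive)), integer(1),
        USE.NAMES = FALSE),
      n_available = length(alive) - 1L
    )
  }
  dplyr::bind_rows(rows) |>
    dplyr::mutate(fraction_met = ifelse(.data$n_available > 0,
                                        .data$n_met / .data$n_available,
                                        NA_real_))
}
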