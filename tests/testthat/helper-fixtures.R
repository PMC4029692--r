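# Fixture builders and independent oracles for the test suite.
# The oracles deliberately avoid the package's internals (no bitmasks, no
# dense tables): plain loops over registry rows and utils::combn subsets.

# A random visibility table drawn directly on the discrete level set.
random_table <- function(seed, n_plants = 3, n_fruits = 3, n_viewpoints = 4,
                         sparsity = 0.3) {
  set.seed(seed)
  registry <- expand.grid(plant_id = sprintf("p%d", seq_len(n_plants)),
                          fruit_id = sprintf("f%d", seq_len(n_fruits)),
                          stringsAsFactors = FALSE)
  grid <- merge(registry, data.frame(viewpoint_label = seq_len(n_viewpoints)))
  keep <- runif(nrow(grid)) > sparsity
  records <- grid[keep, , drop = FALSE]
  records$fv_percent <- sample(fv_levels(), nrow(records), replace = TRUE)
  visibility_table(records, registry,
                   viewpoint_labels = seq_len(n_viewpoints))
}

# Independent per-plant FD: direct count over the registry.
brute_plant_fd <- function(table, plant, vset, threshold) {
  fruits <- table$registry$fruit_id[table$registry$plant_id == plant]
  n_det <- 0
  for (f in fruits) {
    fv <- table$records$fv_percent[
      table$records$plant_id == plant &
        table$records$fruit_id == f &
        table$records$viewpoint_label %in% vset]
    if (length(fv) > 0 && any(fv >= threshold)) n_det <- n_det + 1
  }
  100 * n_det / length(fruits)
}

brute_mean_fd <- function(table, vset, threshold) {
  plants <- unique(table$registry$plant_id)
  mean(vapply(plants, function(p) brute_plant_fd(table, p, vset, threshold),
              numeric(1)))
}

# Independent exhaustive scan over all subsets via utils::combn.
brute_max_fd_by_size <- function(table, labels, threshold, tol = 1e-9) {
  labels <- sort(labels)
  m <- length(labels)
  max_fd <- numeric(m)
  argmax <- vector("list", m)
  for (k in seq_len(m)) {
    subsets <- utils::combn(labels, k, simplify = FALSE)
    fd <- vapply(subsets, function(s) brute_mean_fd(table, s, threshold),
                 numeric(1))
    max_fd[k] <- max(fd)
    argmax[[k]] <- subsets[fd >= max_fd[k] - tol]
  }
  gmax <- max(max_fd)
  list(max_fd = max_fd, argmax = argmax, global_max_fd = gmax,
       positions_needed = min(which(max_fd >= gmax - tol)))
}

# Two-pass textbook sample SD.
two_pass_sd <- function(x) {
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / (length(x) - 1))
}

# A minimal one-plant scene with no leaves, for hand-built occlusion tests.
bare_scene <- function(fruit_at = c(0, 0, 1), radius = 0.04) {
  sc <- generate_scene(scene_params(n_plants = 1, fruits_per_plant = 1,
                                    leaf_density = 0), seed = 1)
  sc$fruits$x <- fruit_at[1]
  sc$fruits$y <- fruit_at[2]
  sc$fruits$z <- fruit_at[3]
  sc$fruits$radius <- radius
  sc$targets$z <- fruit_at[3]
  sc
}

# Append a leaf disc to a scene.
add_disc <- function(scene, centre, normal, axis1, semi_a, semi_b) {
  normal <- normal / sqrt(sum(normal^2))
  axis1 <- axis1 - sum(axis1 * normal) * normal
  axis1 <- axis1 / sqrt(sum(axis1^2))
  scene$leaves <- rbind(scene$leaves, data.frame(
    plant_id = "p01", cx = centre[1], cy = centre[2], cz = centre[3],
    nx = normal[1], ny = normal[2], nz = normal[3],
    a1x = axis1[1], a1y = axis1[2], a1z = axis1[3],
    semi_a = semi_a, semi_b = semi_b))
  scene
}
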