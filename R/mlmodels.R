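# The five trainable heads: partial charges (random forest), atom types /
# torsion phase / torsion periodicity (feed-forward classifiers), and bond
# and angle force constants (random forests on bonded descriptors).
# Train/validation splits are stratified by molecule, never by atom, so a
# molecule's atoms cannot leak across the split.

#' @importFrom ranger ranger
NULL

split_by_molecule <- function(provenance, holdout_frac, seed) {
  mols <- unique(provenance$molecule)
  set.seed(seed)
  n_hold <- max(1L, round(holdout_frac * length(mols)))
  hold <- sample(mols, n_hold)
  list(train = which(!provenance$molecule %in% hold),
       holdout = which(provenance$molecule %in% hold))
}

molecule_folds <- function(provenance, k, seed) {
  mols <- unique(provenance$molecule)
  set.seed(seed + 1L)
  fold_of <- sample(rep_len(seq_len(k), length(mols)))
  names(fold_of) <- mols
  unname(fold_of[provenance$molecule])
}

r_squared <- function(truth, pred) {
  1 - sum((truth - pred)^2) / sum((truth - mean(truth))^2)
}

classification_report <- function(truth, pred) {
  truth <- as.character(truth); pred <- as.character(pred)
  lev <- sort(union(truth, pred))
  truth <- factor(truth, levels = lev)
  pred <- factor(pred, levels = lev)
  cm <- table(truth = truth, pred = pred)
  tp <- diag(cm)
  precision <- ifelse(colSums(cm) > 0, tp / colSums(cm), NA_real_)
  recall <- ifelse(rowSums(cm) > 0, tp / rowSums(cm), NA_real_)
  f1 <- ifelse(precision + recall > 0, 2 * precision * recall /
                 (precision + recall), NA_real_)
  list(accuracy = mean(as.character(truth) == as.character(pred)),
       per_class = data.frame(class = levels(truth), precision = precision,
                              recall = recall, f1 = f1, row.names = NULL),
       confusion = cm)
}

#' Train the partial-charge random forest
#'
#' Fits a random-forest regressor (800 trees, maximum depth 100) on
#' atom-descriptor rows with charge labels in e. 20% of molecules are held
#' out for validation; 5-fold molecule-level cross-validation MSE is
#' reported alongside the held-out MSE and R-squared.
#'
#' @param dataset an atom-kind `TrainingDataset` with numeric charge labels.
#' @param seed RNG seed (splits and forest).
#' @param num_trees,max_depth forest size parameters.
#' @param cv_folds cross-validation folds (0 skips CV).
#' @return list with `model` (a `ChargeModel`) and `report`
#'   (a `TrainingReport`).
#' @export
train_charge_model <- function(dataset, seed = 7L, num_trees = 800L,
                               max_depth = 100L, cv_folds = 5L) {
  if (dataset$kind != "atom") stop("charge model needs an atom dataset")
  n <- nrow(dataset$features)
  if (n < max(cv_folds, 2L)) stop("dataset too small")
  y <- as.numeric(dataset$labels)
  X <- dataset$features
  colnames(X) <- dataset$manifest$feature_names

  sp <- split_by_molecule(dataset$provenance, 0.2, seed)
  dtrain <- data.frame(..y = y[sp$train], X[sp$train, , drop = FALSE],
                       check.names = FALSE)
  fit <- ranger::ranger(dependent.variable.name = "..y", data = dtrain,
                        num.trees = num_trees, max.depth = max_depth,
                        seed = seed, num.threads = 1L)
  pred_hold <- stats::predict(fit, data.frame(
    X[sp$holdout, , drop = FALSE], check.names = FALSE))$predictions
  heldout_mse <- mean((y[sp$holdout] - pred_hold)^2)
  heldout_r2 <- r_squared(y[sp$holdout], pred_hold)

  fold_mse <- numeric(0)
  if (cv_folds > 0L) {
    prov_tr <- dataset$provenance[sp$train, , drop = FALSE]
    folds <- molecule_folds(prov_tr, cv_folds, seed)
    fold_mse <- vapply(seq_len(cv_folds), function(f) {
      tr <- sp$train[folds != f]; te <- sp$train[folds == f]
      d <- data.frame(..y = y[tr], X[tr, , drop = FALSE],
                      check.names = FALSE)
      m <- ranger::ranger(dependent.variable.name = "..y", data = d,
                          num.trees = num_trees, max.depth = max_depth,
                          seed = seed + f, num.threads = 1L)
      p <- stats::predict(m, data.frame(X[te, , drop = FALSE],
                                        check.names = FALSE))$predictions
      mean((y[te] - p)^2)
    }, numeric(1))
  }
  report <- structure(list(per_fold_mse = fold_mse,
                           cv_mean_mse = if (length(fold_mse))
                             mean(fold_mse) else NA_real_,
                           heldout_mse = heldout_mse,
                           heldout_r2 = heldout_r2,
                           n_train = length(sp$train),
                           n_holdout = length(sp$holdout)),
                      class = "TrainingReport")
  model <- structure(list(forest = fit, manifest = dataset$manifest,
                          seed = seed, report = report),
                     class = "ChargeModel")
  list(model = model, report = report)
}

#' Predict raw per-atom partial charges
#'
#' Applies the charge forest to every atom of a molecule. The returned
#' charges are raw model outputs; pass them through [normalize_charges()]
#' before use in a topology.
#'
#' @param model a `ChargeModel`.
#' @param mol perceived `Molecule`.
#' @return numeric vector of charges (e), one per atom.
#' @export
predict_charges <- function(model, mol) {
  man <- model$manifest
  if (!isTRUE(mol$perceived)) mol <- perceive_environment(mol)
  X <- atom_feature_matrix(mol, man)
  colnames(X) <- man$feature_names
  stats::predict(model$forest,
                 data.frame(X, check.names = FALSE))$predictions
}

#' Train a classifier head
#'
#' Trains the feed-forward classifier for one categorical head: GAFF atom
#' types (atom descriptors), torsion phase angle in {0, 180} degrees, or
#' torsion periodicity (torsion descriptors). 20% of molecules are held out;
#' the report carries held-out accuracy and per-class precision/recall/F1.
#'
#' @param head `"atomtype"`, `"phase"` or `"periodicity"`.
#' @param dataset a `TrainingDataset` with categorical labels.
#' @param seed RNG seed.
#' @param hidden hidden-layer sizes of the classifier.
#' @param epochs,batch training schedule.
#' @return list with `model` (a `ClassifierModel`) and `report`.
#' @export
train_classifier <- function(head = c("atomtype", "phase", "periodicity"),
                             dataset, seed = 7L, hidden = c(256L, 128L),
                             epochs = 60L, batch = 32L) {
  head <- match.arg(head)
  y <- factor(dataset$labels)
  if (nlevels(droplevels(y)) < 2L) stop("degenerate labels")
  if (head == "phase" &&
      !all(levels(y) %in% c("0", "180")))
    stop("phase labels must be 0 or 180 degrees")
  X <- dataset$features
  sp <- split_by_molecule(dataset$provenance, 0.2, seed)
  fit <- mlp_fit(X[sp$train, , drop = FALSE], droplevels(y[sp$train]),
                 hidden = hidden, epochs = epochs, batch = batch,
                 seed = seed)
  pred <- predict(fit, X[sp$holdout, , drop = FALSE])
  rep_ <- classification_report(as.character(y[sp$holdout]),
                                as.character(pred))
  report <- structure(list(accuracy = rep_$accuracy,
                           per_class = rep_$per_class,
                           confusion = rep_$confusion,
                           n_train = length(sp$train),
                           n_holdout = length(sp$holdout)),
                      class = "TrainingReport")
  model <- structure(list(net = fit, head = head, classes = fit$classes,
                          manifest = dataset$manifest, seed = seed,
                          report = report),
                     class = "ClassifierModel")
  list(model = model, report = report)
}

#' Predict GAFF atom types with the classifier head
#'
#' @param model a `ClassifierModel` with `head == "atomtype"`.
#' @param mol perceived `Molecule`.
#' @return character vector of predicted type codes.
#' @export
predict_atom_types <- function(model, mol) {
  stopifnot(model$head == "atomtype")
  man <- model$manifest
  if (!isTRUE(mol$perceived)) mol <- perceive_environment(mol)
  X <- atom_feature_matrix(mol, man)
  as.character(predict(model$net, X))
}

#' Predict torsion phase and periodicity
#'
#' Applies the phase and periodicity heads to every proper torsion of a
#' molecule. A torsion and its reversal share one canonical descriptor, so
#' they always receive the same parameters.
#'
#' @param models list with elements `phase` and `periodicity`
#'   (`ClassifierModel`s).
#' @param mol perceived `Molecule`.
#' @return data.frame with columns i, j, k, l, phase (degrees), periodicity.
#' @export
predict_torsion_params <- function(models, mol) {
  if (!isTRUE(mol$perceived)) mol <- perceive_environment(mol)
  tors <- internal_coordinates(mol)$torsions
  if (nrow(tors) == 0L)
    return(data.frame(i = integer(), j = integer(), k = integer(),
                      l = integer(), phase = numeric(),
                      periodicity = integer()))
  man <- models$phase$manifest
  af <- atom_feature_matrix(mol, man)
  X <- t(vapply(seq_len(nrow(tors)), function(r)
    torsion_row(af, c(tors$i[r], tors$j[r], tors$k[r], tors$l[r]),
                tors$phi[r]),
    numeric(4L * man$width + 1L)))
  data.frame(tors[, c("i", "j", "k", "l")],
             phase = as.numeric(as.character(predict(models$phase$net, X))),
             periodicity =
               as.integer(as.character(predict(models$periodicity$net, X))))
}

# ---- force constants -------------------------------------------------------

# datasets for the bond/angle force-constant regressors
build_bond_dataset <- function(mols, label_fun = NULL) {
  feats <- list(); labs <- list(); prov <- list()
  for (mol in mols) {
    if (!isTRUE(mol$perceived)) mol <- perceive_environment(mol)
    b <- mol$bonds
    if (nrow(b) == 0L) next
    rb <- ref_block_matrix(mol)
    f <- t(vapply(seq_len(nrow(b)), function(e)
      featurize_bond(mol, b$i[e], b$j[e], rb), numeric(46L)))
    y <- if (is.null(label_fun)) {
      vapply(seq_len(nrow(b)), function(e)
        bond_k_label(mol$atoms$element[b$i[e]], mol$atoms$element[b$j[e]],
                     if (b$aromatic[e]) "ar" else b$order[e]), numeric(1))
    } else label_fun(mol)
    feats[[length(feats) + 1L]] <- f
    labs[[length(labs) + 1L]] <- y
    prov[[length(prov) + 1L]] <- data.frame(molecule = mol$name,
                                            row_id = seq_len(nrow(b)))
  }
  structure(list(features = do.call(rbind, feats),
                 labels = do.call(c, labs),
                 provenance = do.call(rbind, prov), kind = "bond"),
            class = "TrainingDataset")
}

build_angle_dataset <- function(mols, label_fun = NULL) {
  feats <- list(); labs <- list(); prov <- list()
  for (mol in mols) {
    if (!isTRUE(mol$perceived)) mol <- perceive_environment(mol)
    ang <- internal_coordinates(mol)$angles
    if (nrow(ang) == 0L) next
    rb <- ref_block_matrix(mol)
    f <- t(vapply(seq_len(nrow(ang)), function(r)
      featurize_angle(mol, ang$i[r], ang$j[r], ang$k[r], rb), numeric(67L)))
    y <- if (is.null(label_fun)) {
      vapply(seq_len(nrow(ang)), function(r)
        angle_k_label(mol$atoms$element[ang$j[r]],
                      mol$atoms$hybridization[ang$j[r]],
                      mol$atoms$element[c(ang$i[r], ang$k[r])]), numeric(1))
    } else label_fun(mol)
    feats[[length(feats) + 1L]] <- f
    labs[[length(labs) + 1L]] <- y
    prov[[length(prov) + 1L]] <- data.frame(molecule = mol$name,
                                            row_id = seq_len(nrow(ang)))
  }
  structure(list(features = do.call(rbind, feats),
                 labels = do.call(c, labs),
                 provenance = do.call(rbind, prov), kind = "angle"),
            class = "TrainingDataset")
}

#' Train the bond/angle force-constant regressors
#'
#' Random forests mapping bonded descriptors to stretch constants K_b
#' (kcal/mol/A^2) and bend constants K_theta (kcal/mol/rad^2).
#'
#' @param bond_dataset,angle_dataset datasets from the bonded featurizers.
#' @param seed RNG seed.
#' @param num_trees forest size.
#' @return a `ForceConstantModel`.
#' @export
train_force_constant_model <- function(bond_dataset, angle_dataset,
                                       seed = 7L, num_trees = 300L) {
  fit_one <- function(ds, s) {
    d <- data.frame(..y = ds$labels, ds$features, check.names = FALSE)
    ranger::ranger(dependent.variable.name = "..y", data = d,
                   num.trees = num_trees, seed = s, num.threads = 1L)
  }
  structure(list(bond = fit_one(bond_dataset, seed),
                 angle = fit_one(angle_dataset, seed + 1L),
                 seed = seed),
            class = "ForceConstantModel")
}

#' Predict bond and angle force constants
#'
#' Equilibrium values are not predicted: bond r_0 and angle theta_0 are
#' taken from the structure geometry.
#'
#' @param model a `ForceConstantModel`.
#' @param mol perceived `Molecule`.
#' @return list with data.frames `bonds` (i, j, r0, kb) and `angles`
#'   (i, j, k, theta0, ktheta); constants strictly positive.
#' @export
predict_force_constants <- function(model, mol) {
  if (!isTRUE(mol$perceived)) mol <- perceive_environment(mol)
  ic <- internal_coordinates(mol)
  b <- mol$bonds
  rb <- ref_block_matrix(mol)
  kb <- if (nrow(b) > 0L) {
    X <- t(vapply(seq_len(nrow(b)), function(e)
      featurize_bond(mol, b$i[e], b$j[e], rb), numeric(46L)))
    stats::predict(model$bond,
                   data.frame(X, check.names = FALSE))$predictions
  } else numeric()
  ang <- ic$angles
  kth <- if (nrow(ang) > 0L) {
    X <- t(vapply(seq_len(nrow(ang)), function(r)
      featurize_angle(mol, ang$i[r], ang$j[r], ang$k[r], rb), numeric(67L)))
    stats::predict(model$angle,
                   data.frame(X, check.names = FALSE))$predictions
  } else numeric()
  list(bonds = data.frame(i = b$i, j = b$j, r0 = b$length, kb = kb),
       angles = data.frame(ang[, c("i", "j", "k")], theta0 = ang$theta,
                           ktheta = kth))
}

# ---- bundle ----------------------------------------------------------------

#' Build the full training set from fixtures
#'
#' Labels every atom and torsion of the fixture set with the synthetic
#' oracles: EEM charges, rule-based GAFF atom types, convention-table
#' torsion phase/periodicity, and surrogate bond/angle force constants.
#'
#' @param fixtures list of perceived `Molecule`s (see [fixture_molecules()]).
#' @param params `EEMParameters` for the charge oracle.
#' @param manifest descriptor manifest.
#' @return named list of `TrainingDataset`s: charges, atomtype, phase,
#'   periodicity, bond_fc, angle_fc.
#' @export
make_training_set <- function(fixtures, params = eem_parameters(),
                              manifest = default_manifest()) {
  # atom features are computed once and shared by the charge and atom-type
  # heads; torsion features once for the phase and periodicity heads
  charges <- build_dataset(fixtures, function(m) eem_charges(m, params),
                           kind = "atom", manifest = manifest)
  atomtype <- charges
  atomtype$labels <- unlist(lapply(fixtures, function(m)
    assign_atom_types(if (isTRUE(m$perceived)) m else
      perceive_environment(m))), use.names = FALSE)
  phase <- build_dataset(fixtures, function(m) {
    tors <- internal_coordinates(m)$torsions
    vapply(seq_len(nrow(tors)), function(r)
      torsion_convention(m, tors$j[r], tors$k[r])$phase, numeric(1))
  }, kind = "torsion", manifest = manifest)
  periodicity <- phase
  periodicity$labels <- unlist(lapply(fixtures, function(m) {
    m <- if (isTRUE(m$perceived)) m else perceive_environment(m)
    tors <- internal_coordinates(m)$torsions
    if (nrow(tors) == 0L) return(NULL)
    vapply(seq_len(nrow(tors)), function(r)
      torsion_convention(m, tors$j[r], tors$k[r])$periodicity, integer(1))
  }), use.names = FALSE)
  list(charges = charges, atomtype = atomtype, phase = phase,
       periodicity = periodicity,
       bond_fc = build_bond_dataset(fixtures),
       angle_fc = build_angle_dataset(fixtures))
}

#' Train all five model heads
#'
#' Convenience wrapper producing a `ModelBundle`: charge forest, atom-type /
#' phase / periodicity classifiers, force-constant regressors, and the
#' descriptor manifest they were trained with.
#'
#' @param fixtures list of perceived `Molecule`s.
#' @param seed RNG seed shared (with fixed offsets) by all heads.
#' @param params EEM oracle parameters.
#' @param manifest descriptor manifest.
#' @param charge_trees,cv_folds charge-forest size and CV folds.
#' @param epochs classifier training epochs.
#' @return a `ModelBundle` with a `reports` element.
#' @export
train_model_bundle <- function(fixtures, seed = 7L,
                               params = eem_parameters(),
                               manifest = default_manifest(),
                               charge_trees = 800L, cv_folds = 5L,
                               epochs = 60L) {
  ds <- make_training_set(fixtures, params, manifest)
  ch <- train_charge_model(ds$charges, seed = seed,
                           num_trees = charge_trees, cv_folds = cv_folds)
  at <- train_classifier("atomtype", ds$atomtype, seed = seed,
                         epochs = epochs)
  ph <- train_classifier("phase", ds$phase, seed = seed, epochs = epochs)
  pe <- train_classifier("periodicity", ds$periodicity, seed = seed,
                         epochs = epochs)
  fc <- train_force_constant_model(ds$bond_fc, ds$angle_fc, seed = seed)
  structure(list(charge = ch$model, atomtype = at$model, phase = ph$model,
                 periodicity = pe$model, fc = fc, manifest = manifest,
                 seed = seed,
                 reports = list(charge = ch$report, atomtype = at$report,
                                phase = ph$report,
                                periodicity = pe$report)),
            class = "ModelBundle")
}

#' @export
print.ModelBundle <- function(x, ...) {
  cat("<ModelBundle>\n")
  cat(sprintf("  charge head:      held-out R2 %.3f, MSE %.4g e^2\n",
              x$reports$charge$heldout_r2, x$reports$charge$heldout_mse))
  cat(sprintf("  atom types:       held-out accuracy %.3f\n",
              x$reports$atomtype$accuracy))
  cat(sprintf("  torsion phase:    held-out accuracy %.3f\n",
              x$reports$phase$accuracy))
  cat(sprintf("  periodicity:      held-out accuracy %.3f\n",
              x$reports$periodicity$accuracy))
  invisible(x)
}
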