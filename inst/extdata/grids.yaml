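# Hyperparameter search domains per algorithm.
# "full" spans the published test ranges; "reduced" is the package default
# used by run_evaluation(), sized for routine re-runs; "default" is the
# untuned spec fitted at the "trained" stage.
# Grids enumerate deterministically: the first listed dimension varies
# fastest, in the listed value order.
svm_linear:
  full:    {C: [0.1, 1, 10, 100, 1000, 10000]}
  reduced: {C: [0.1, 1, 100]}
  default: {C: 1.0}
svm_poly:
  full:    {C: [0.1, 1, 10, 100, 1000, 10000], c1: [2, 3], c0: [0, 1]}
  reduced: {C: [1, 1000], c1: [2, 3], c0: [1]}
  default: {C: 1000, c1: 3, c0: 1}
svm_rbf:
  full:    {C: [0.1, 1, 10, 100, 1000, 10000]}
  reduced: {C: [0.1, 1, 100]}
  default: {C: 1.0}
svm_sigmoid:
  full:    {C: [0.0001, 0.001, 0.01, 0.1, 1, 10, 100, 2000], c0: [0, 0.01, 0.5, 1]}
  reduced: {C: [0.0001, 0.1, 1], c0: [0]}
  default: {C: 0.0001, c0: 0}
knn:
  full:    {k: [2, 3, 4, 5, 6, 7, 8, 9, 10, 11], weight: [uniform, distance]}
  reduced: {k: [2, 5, 10], weight: [uniform, distance]}
  default: {k: 10, weight: uniform}
logistic:
  full:    {C: [0.001, 0.01, 0.1, 1, 10, 100, 1000, 20000]}
  reduced: {C: [0.001, 1, 1000]}
  default: {C: 1.0}
decision_tree:
  full:
    D: [3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14]
    n_s: [3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14, 15, 16, 17, 18, 19]
    n_r: [2, 3, 4, 5, 6]
    impurity: [gini, entropy]
  reduced: {D: [3, 8, 14], n_s: [3], n_r: [2], impurity: [gini, entropy]}
  default: {D: 4, n_s: 3, n_r: 2, impurity: entropy}
random_forest:
  # the forest backend exposes no min-samples-to-split knob; the n_s range
  # of the source table is therefore not part of the shipped grid, and the
  # impurity criterion is fixed at Gini
  full:    {n_f: [10, 60, 110], D: [1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11], n_r: [2, 3, 4, 5, 6]}
  reduced: {n_f: [10, 60], D: [5, 11], n_r: [2]}
  default: {n_f: 60, D: 2, n_r: 1}
mlp:
  full:
    total_neurons: [100, 200]
    ratio: ["1", "1:8:1", "1:4:4:1", "1:2:2:2:2:1"]
    activation: [identity, logistic, tanh, relu]
    solver: [lbfgs, sgd, adam]
    learning_rate: [constant, invscaling, adaptive]
    C: [0.0001, 0.05, 1]
  reduced:
    total_neurons: [100]
    ratio: ["1"]
    activation: [identity, relu]
    solver: [lbfgs]
    learning_rate: [constant]
    C: [0.0001]
  default:
    total_neurons: 200
    ratio: "1:8:1"
    activation: relu
    solver: lbfgs
    learning_rate: constant
    C: 0.0001
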