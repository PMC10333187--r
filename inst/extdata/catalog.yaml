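# Declarative catalog of disease and procedure transformations.
#
# Each entry is an ordered edit script over the canonical 24-vertex
# circulation graph.  Vertex endpoints are 1-based canonical indices;
# "new" refers to the vertex most recently created by an add_vertex step
# (new vertices always take index n+1).  Steps may carry a `when` clause
# keyed on a declared parameter; the step is applied only when the
# parameter's resolved value is in the listed set.  `asserts` are matrix
# cells whose printed values are verified (not edited) after application.
#
# Users may register additional conditions by shipping a file in this
# schema and loading it with load_catalog().

diseases:
  PDA:
    category: increased_vertices
    description: patent ductus arteriosus, a persisting fetal channel from
      the descending aorta to the pulmonary trunk
    steps:
      - {op: add_vertex, abbr: PDA, name: patent ductus arteriosus, compartment: shunt}
      - {op: add_edge, from: 18, to: new}
      - {op: add_edge, from: new, to: 5}
  MAPCA:
    category: increased_vertices
    description: major aortopulmonary collateral artery from the descending
      aorta to one lung
    parameters:
      lung: {default: right, choices: [right, left]}
    steps:
      - {op: add_vertex, abbr: MAPCA, name: major aortopulmonary collateral artery, compartment: collateral}
      - {op: add_edge, from: 18, to: new}
      - {op: add_edge, from: new, to: 8, when: {lung: [right]}}
      - {op: add_edge, from: new, to: 9, when: {lung: [left]}}
  PLSVC:
    category: increased_vertices
    description: persistent left superior vena cava draining to the right atrium
    steps:
      - {op: add_vertex, abbr: PLSVC, name: persistent left superior vena cava, compartment: systemic_vein}
      - {op: add_edge, from: new, to: 3}
  absent_pulmonary_artery:
    category: decreased_vertices
    description: isolated unilateral absence of a pulmonary artery; the
      vertex is kept but isolated, which is equivalent to its removal
    parameters:
      side: {default: right, choices: [right, left]}
    steps:
      - {op: remove_edge, from: 5, to: 6, when: {side: [right]}}
      - {op: remove_edge, from: 6, to: 8, when: {side: [right]}}
      - {op: remove_edge, from: 5, to: 7, when: {side: [left]}}
      - {op: remove_edge, from: 7, to: 9, when: {side: [left]}}
  ASD:
    category: increased_edges
    description: atrial septal defect, a shunt between the atria
    parameters:
      direction: {default: bidirectional, choices: [left_to_right, right_to_left, bidirectional]}
    steps:
      - {op: add_edge, from: 3, to: 14, when: {direction: [right_to_left, bidirectional]}}
      - {op: add_edge, from: 14, to: 3, when: {direction: [left_to_right, bidirectional]}}
  VSD:
    category: increased_edges
    description: ventricular septal defect, a shunt between the ventricles
    parameters:
      direction: {default: bidirectional, choices: [left_to_right, right_to_left, bidirectional]}
    steps:
      - {op: add_edge, from: 4, to: 15, when: {direction: [right_to_left, bidirectional]}}
      - {op: add_edge, from: 15, to: 4, when: {direction: [left_to_right, bidirectional]}}
  aortopulmonary_septal_defect:
    category: increased_edges
    description: communication between the pulmonary trunk and ascending aorta
    parameters:
      direction: {default: bidirectional, choices: [left_to_right, right_to_left, bidirectional]}
    steps:
      - {op: add_edge, from: 5, to: 16, when: {direction: [right_to_left, bidirectional]}}
      - {op: add_edge, from: 16, to: 5, when: {direction: [left_to_right, bidirectional]}}
  tricuspid_atresia:
    category: decreased_edges
    description: no flow from the right atrium to the right ventricle
    steps:
      - {op: remove_edge, from: 3, to: 4}
  pulmonary_atresia:
    category: decreased_edges
    description: no flow from the right ventricle to the pulmonary trunk
    steps:
      - {op: remove_edge, from: 4, to: 5}
  anomalous_pulmonary_venous_return:
    category: abnormal_connections
    description: a pulmonary vein drains somewhere other than the left atrium
    parameters:
      vein: {default: 10, choices: [10, 11, 12, 13]}
      target: {default: 3, forbid: [14]}
    steps:
      - {op: remove_edge, from: $vein, to: 14}
      - {op: add_edge, from: $vein, to: $target}
  d-TGA:
    category: abnormal_connections
    description: ventriculoarterial discordance (RV to AAo, LV to PT),
      equivalent to interchanging the PT and AAo columns
    steps:
      - {op: interchange_columns, j: 5, k: 16}
    asserts:
      - {i: 3, j: 4, value: 1}
      - {i: 3, j: 15, value: 0}
      - {i: 14, j: 15, value: 1}
      - {i: 14, j: 4, value: 0}
  l-TGA:
    category: abnormal_connections
    description: atrioventricular plus ventriculoarterial discordance,
      interchanging the RV/LV and PT/AAo columns
    steps:
      - {op: interchange_columns, j: 4, k: 15}
      - {op: interchange_columns, j: 5, k: 16}
  DORV:
    category: abnormal_connections
    description: double outlet right ventricle; both great arteries arise
      from the right ventricle
    steps:
      - {op: add_edge, from: 4, to: 16}
      - {op: remove_edge, from: 15, to: 16}
    asserts:
      - {i: 4, j: 5, value: 1}
      - {i: 15, j: 5, value: 0}
  truncus_arteriosus:
    category: abnormal_connections
    description: a single common trunk receives both ventricles and feeds
      the pulmonary trunk; vertex 16 is relabeled
    steps:
      - {op: relabel_vertex, index: 16, abbr: TrA, name: truncus arteriosus}
      - {op: remove_edge, from: 4, to: 5}
      - {op: add_edge, from: 4, to: 16}
      - {op: add_edge, from: 16, to: 5}
    asserts:
      - {i: 15, j: 16, value: 1}
      - {i: 15, j: 5, value: 0}

procedures:
  right_mBT_shunt:
    category: procedure
    description: right modified Blalock-Taussig shunt from the right
      subclavian artery to the right pulmonary artery
    steps:
      - {op: add_vertex, abbr: mBT, name: modified Blalock-Taussig shunt, compartment: shunt}
      - {op: add_edge, from: 23, to: new}
      - {op: add_edge, from: new, to: 6}
  left_mBT_shunt:
    category: procedure
    description: left modified Blalock-Taussig shunt from the left
      subclavian artery to the left pulmonary artery
    steps:
      - {op: add_vertex, abbr: mBT, name: modified Blalock-Taussig shunt, compartment: shunt}
      - {op: add_edge, from: 21, to: new}
      - {op: add_edge, from: new, to: 7}
  norwood_with_right_mBT:
    category: procedure
    description: Norwood palliation; the pulmonary trunk is detached from
      the branch pulmonary arteries and joined to the ascending aorta, with
      pulmonary flow supplied by a right mBT shunt
    steps:
      - {op: remove_edge, from: 5, to: 6}
      - {op: remove_edge, from: 5, to: 7}
      - {op: add_edge, from: 5, to: 16}
      - {op: add_vertex, abbr: mBT, name: modified Blalock-Taussig shunt, compartment: shunt}
      - {op: add_edge, from: 23, to: new}
      - {op: add_edge, from: new, to: 6}
      - {op: add_edge, from: 6, to: 7}
  bidirectional_glenn:
    category: procedure
    description: superior vena cava detached from the right atrium and
      anastomosed to the right pulmonary artery
    steps:
      - {op: remove_edge, from: 1, to: 3}
      - {op: add_edge, from: 1, to: 6}
  fontan:
    category: procedure
    description: inferior vena cava routed directly to the right pulmonary
      artery, completing cavopulmonary circulation
    steps:
      - {op: remove_edge, from: 2, to: 3}
      - {op: add_edge, from: 2, to: 6}
  arterial_switch:
    category: procedure
    description: restores ventriculoarterial concordance by interchanging
      the PT and AAo columns
    steps:
      - {op: interchange_columns, j: 5, k: 16}
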