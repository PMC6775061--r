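9.0133359608137087e-01	1.8306301170089804e-02	4.8530749995226536e-03	7.9868226942168326e-03	6.4611427607554298e-02	2.9087774472455401e-03
9.1531505850449019e-03	5.0000000000000000e-01	2.8471203963861260e-03	3.7560523877329194e-01	9.0709937199385055e-02	2.1684553045891956e-02
2.9412575754682747e-04	3.4510550259225770e-04	9.4823417285614797e-01	3.0750512025548148e-02	1.3030137722573026e-05	2.0363053720442243e-02
2.6921874250169099e-04	2.5321701490334293e-02	1.7102812868141949e-02	9.5304658482174620e-01	3.3699277102626759e-03	8.8975436701318805e-04
1.2152619612706139e-03	3.4122860388483404e-03	4.0438358449364569e-06	1.8803985342531544e-03	9.8652925826143067e-01	6.9587513683523235e-03
4.5449647613211563e-05	6.7764228268412361e-04	5.2498497873015157e-03	4.1243822220923820e-04	5.7808377252718517e-03	9.8783378233492003e-01
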