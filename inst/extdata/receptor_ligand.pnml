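<?xml version="1.0" encoding="UTF-8"?>
<pnml xmlns="http://www.pnml.org/version-2009/grammar/pnml">
  <net id="receptor_ligand" type="http://www.pnml.org/version-2009/grammar/ptnet">
    <toolspecific tool="adspn" version="0.1">
      <semantics>constant_hazard</semantics>
      <param name="d1" value="1"/>
      <param name="d2" value="1"/>
    </toolspecific>
    <page id="page0">
      <place id="Receptor">
        <name>
          <text>Receptor</text>
        </name>
        <initialMarking>
          <text>1</text>
        </initialMarking>
      </place>
      <place id="Open_R">
        <name>
          <text>Open_R</text>
        </name>
        <initialMarking>
          <text>0</text>
        </initialMarking>
      </place>
      <place id="Ligand">
        <name>
          <text>Ligand</text>
        </name>
        <initialMarking>
          <text>1</text>
        </initialMarking>
      </place>
      <place id="Active_L">
        <name>
          <text>Active_L</text>
        </name>
        <initialMarking>
          <text>0</text>
        </initialMarking>
      </place>
      <place id="RL_Complex">
        <name>
          <text>RL_Complex</text>
        </name>
        <initialMarking>
          <text>0</text>
        </initialMarking>
      </place>
      <transition id="Opening">
        <name>
          <text>Opening</text>
        </name>
        <toolspecific tool="adspn" version="0.1">
          <rate>1</rate>
        </toolspecific>
      </transition>
      <transition id="Activation">
        <name>
          <text>Activation</text>
        </name>
        <toolspecific tool="adspn" version="0.1">
          <rate>1</rate>
        </toolspecific>
      </transition>
      <transition id="Binding">
        <name>
          <text>Binding</text>
        </name>
        <toolspecific tool="adspn" version="0.1">
          <rate>1</rate>
        </toolspecific>
      </transition>
      <arc id="a1" source="Receptor" target="Opening">
        <inscription>
          <text>1</text>
        </inscription>
        <toolspecific tool="adspn" version="0.1">
          <kind>standard</kind>
        </toolspecific>
      </arc>
      <arc id="a2" source="Opening" target="Open_R">
        <inscription>
          <text>1</text>
        </inscription>
        <toolspecific tool="adspn" version="0.1">
          <kind>standard</kind>
        </toolspecific>
      </arc>
      <arc id="a3" source="Ligand" target="Activation">
        <inscription>
          <text>1</text>
        </inscription>
        <toolspecific tool="adspn" version="0.1">
          <kind>standard</kind>
        </toolspecific>
      </arc>
      <arc id="a4" source="Activation" target="Active_L">
        <inscription>
          <text>1</text>
        </inscription>
        <toolspecific tool="adspn" version="0.1">
          <kind>standard</kind>
        </toolspecific>
      </arc>
      <arc id="a5" source="Open_R" target="Binding">
        <inscription>
          <text>1</text>
        </inscription>
        <toolspecific tool="adspn" version="0.1">
          <kind>standard</kind>
        </toolspecific>
      </arc>
      <arc id="a6" source="Active_L" target="Binding">
        <inscription>
          <text>1</text>
        </inscription>
        <toolspecific tool="adspn" version="0.1">
          <kind>standard</kind>
        </toolspecific>
      </arc>
      <arc id="a7" source="Binding" target="RL_Complex">
        <inscription>
          <text>1</text>
        </inscription>
        <toolspecific tool="adspn" version="0.1">
          <kind>standard</kind>
        </toolspecific>
      </arc>
    </page>
  </net>
</pnml>
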