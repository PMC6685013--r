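<?xml version="1.0" encoding="UTF-8"?>
<rsml>
  <metadata>
    <version>1</version>
    <software>synthetic (hand-written example, not a real tracing)</software>
    <resolution>10</resolution>
    <unit>mm</unit>
  </metadata>
  <scene>
    <plant id="example">
      <root id="primary">
        <geometry>
          <polyline>
            <point x="0" y="0"/>
            <point x="2" y="120"/>
            <point x="0" y="260"/>
            <point x="-3" y="410"/>
          </polyline>
        </geometry>
        <root id="lateral-1">
          <geometry>
            <polyline>
              <point x="2" y="118"/>
              <point x="40" y="130"/>
              <point x="74" y="141"/>
            </polyline>
          </geometry>
        </root>
        <root id="lateral-2">
          <geometry>
            <polyline>
              <point x="0" y="258"/>
              <point x="-35" y="276"/>
            </polyline>
          </geometry>
        </root>
      </root>
    </plant>
  </scene>
</rsml>
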